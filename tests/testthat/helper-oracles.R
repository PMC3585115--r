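# Independent brute-force oracles and tiny fixtures. These deliberately
# avoid the package's computational path: scores are accumulated with an
# explicit per-position loop, occupancies by filtering all 2^n subsets,
# and Markov steady states by a dense linear solve.

toy_pwm <- function(consensus = "ACG", tf = "toy", strong = 10,
                    pseudocount = 1) {
  chars <- strsplit(consensus, "")[[1]]
  counts <- matrix(0, length(chars), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <-
    strong
  build_pwm(counts, tf = tf, pseudocount = pseudocount)
}

# Per-window score by explicit position-wise accumulation.
oracle_window_score <- function(seq, pwm, offset) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (i in seq_len(pwm$width)) {
    b <- match(chars[offset + i], c("A", "C", "G", "T"))
    if (is.na(b)) return(-Inf)
    total <- total + unname(pwm$logodds[i, b])
  }
  total
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Exact occupancies by global enumeration of every subset of sites,
# keeping only subsets with no overlapping footprints; no grouping.
oracle_occupancy <- function(fp_start, fp_end, q, pairs = NULL, omega = 1) {
  n <- length(q)
  stopifnot(length(fp_start) == n, length(fp_end) == n)
  f <- numeric(n)
  z <- 0
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      for (a in members) {
        for (b in members) {
          if (a < b && fp_start[a] < fp_end[b] && fp_start[b] < fp_end[a]) {
            ok <- FALSE
          }
        }
      }
    }
    if (!ok) next
    w <- prod(q[members])
    if (!is.null(pairs) && nrow(pairs) > 0) {
      for (p in seq_len(nrow(pairs))) {
        if (pairs$site_a[p] %in% members && pairs$site_b[p] %in% members) {
          w <- w * omega
        }
      }
    }
    z <- z + w
    f[members] <- f[members] + w
  }
  f / z
}

# Random site geometries for property tests: n sites with random
# footprints on a short construct, random affinities/weights.
random_site_set <- function(n, len = 300) {
  start <- sort(sample.int(len - 20, n))
  width <- sample(8:14, n, replace = TRUE)
  tibble::tibble(
    site_id = seq_len(n),
    tf = sample(c("Bcd", "Kr", "Hb"), n, replace = TRUE),
    start = start, end = start + width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    score = stats::runif(n, -2, 2),
    rel_affinity = stats::runif(n, 0.05, 1),
    fp_start = pmax(0L, start - 2L),
    fp_end = pmin(len, start + width + 2L),
    center = start + width / 2
  )
}

# Markov steady state via a dense linear solve of the balance equations.
oracle_three_state <- function(k1, km1, k2, k3) {
  A <- rbind(c(-k1, km1, k3),
             c(k1, -(km1 + k2), 0),
             c(1, 1, 1))
  solve(A, c(0, 0, 1))
}

# Shared small fixtures for pipeline-level tests.
fixture_config <- function() default_model_config()
fixture_pwms <- function() synthetic_pwms()
fixture_profiles <- function() generate_profiles()
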