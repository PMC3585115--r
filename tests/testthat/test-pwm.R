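test_that("log-odds construction follows the count-normalization formula", {
  # uniform column: matches background exactly, all log-odds zero
  counts <- matrix(25, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- build_pwm(counts, pseudocount = 0)
  expect_equal(unname(pwm$logodds), matrix(0, 3, 4))
  expect_equal(pwm$max_score, 0)

  # single observed base, no pseudocount: log(1/0.25) for that base
  counts1 <- matrix(c(10, 0, 0, 0), 1, 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm1 <- build_pwm(counts1, pseudocount = 1e-12)
  expect_equal(unname(pwm1$logodds[1, "A"]), log(4), tolerance = 1e-9)

  # hand arithmetic: counts (8,1,1,0), pseudocount 1 -> A = log((9/14)/.25)
  counts2 <- matrix(c(8, 1, 1, 0), 1, 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm2 <- build_pwm(counts2, pseudocount = 1)
  expect_equal(unname(pwm2$logodds[1, "A"]), log((9 / 14) / 0.25))
  expect_equal(unname(pwm2$logodds[1, "T"]), log((1 / 14) / 0.25))

  # max_score is the consensus score
  pwm3 <- toy_pwm("ACGT")
  expect_equal(pwm3$max_score,
               oracle_window_score("ACGT", pwm3, 0))
  expect_equal(pwm3$consensus, "ACGT")
})

test_that("degenerate columns and invalid backgrounds are rejected", {
  counts <- matrix(c(10, 0, 0, 0), 1, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(build_pwm(counts, pseudocount = 0), "degenerate")
  expect_error(build_pwm(counts, background = c(0.5, 0.5, 0, 0)),
               "background")
  expect_error(build_pwm(counts, pseudocount = -1), "pseudocount")
})

test_that("count tables are accepted in both orientations", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 10, 0, 0), ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  a <- build_pwm(counts)
  b <- build_pwm(t(counts))  # 4 x width, unlabeled
  rownames(counts) <- NULL
  cc <- counts
  cc2 <- t(cc)
  rownames(cc2) <- c("A", "C", "G", "T")
  c_ <- build_pwm(cc2)       # labeled base rows
  expect_equal(a$logodds, b$logodds)
  expect_equal(a$logodds, c_$logodds)
})

test_that("score-to-affinity is exp(lambda * (score - max))", {
  pwm <- toy_pwm("ACG")
  expect_equal(score_to_affinity(pwm$max_score, pwm, 2.3), 1)
  expect_equal(score_to_affinity(-5, pwm, 0), 1)
  expect_equal(score_to_affinity(pwm$max_score - 2, pwm, 1), exp(-2))
  expect_error(score_to_affinity(pwm$max_score + 1, pwm, 1),
               "inconsistent")
  # strict monotonicity in score for positive lambda
  s <- seq(pwm$max_score - 4, pwm$max_score, length.out = 9)
  aff <- score_to_affinity(s, pwm, 0.7)
  expect_true(all(diff(aff) > 0))
  expect_true(all(aff > 0 & aff <= 1))
})

test_that("scanning finds planted sites on both strands with forward coordinates", {
  pwm <- toy_pwm("ACGTAC")
  bg <- "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT"
  seq_fwd <- paste0(substr(bg, 1, 10), "ACGTAC", substr(bg, 1, 10))
  hits <- scan_sequence(seq_fwd, pwm, threshold = pwm$max_score - 0.5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 16L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$rel_affinity, 1)

  seq_rev <- paste0(substr(bg, 1, 5), oracle_revcomp("ACGTAC"),
                    substr(bg, 1, 10))
  hits_r <- scan_sequence(seq_rev, pwm, threshold = pwm$max_score - 0.5)
  expect_equal(nrow(hits_r), 1L)
  expect_equal(hits_r$start, 5L)
  expect_equal(hits_r$strand, "-")
})

test_that("a palindromic consensus yields hits on both strands at one interval", {
  pwm <- toy_pwm("ACGT")  # reverse complement of ACGT is ACGT
  seq <- paste0("TTTTTTTT", "ACGT", "TTTTTTTT")
  hits <- scan_sequence(seq, pwm, threshold = pwm$max_score - 0.5)
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$start), 8L)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("window scores match the per-position brute-force oracle", {
  set.seed(11)
  pwm <- toy_pwm("TGACA", strong = 7)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  hits <- scan_sequence(seq, pwm, threshold = -Inf)
  fwd <- hits[hits$strand == "+", ]
  for (k in seq_len(nrow(fwd))) {
    expect_equal(fwd$score[k],
                 oracle_window_score(seq, pwm, fwd$start[k]),
                 tolerance = 1e-12)
  }
  # minus-strand scores equal plus-strand scores of the reverse complement
  rc <- oracle_revcomp(seq)
  hits_rc <- scan_sequence(rc, pwm, threshold = -Inf)
  L <- nchar(seq)
  rev_as_fwd <- hits_rc[hits_rc$strand == "+", ]
  mapped_start <- L - rev_as_fwd$end
  minus <- hits[hits$strand == "-", ]
  expect_equal(sort(minus$score),
               sort(rev_as_fwd$score[order(mapped_start)]))
})

test_that("strand symmetry: scanning the reverse complement reflects the site set", {
  set.seed(7)
  pwm <- toy_pwm("GATTACA")
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    L <- nchar(seq)
    a <- scan_sequence(seq, pwm, threshold = -5)
    b <- scan_sequence(oracle_revcomp(seq), pwm, threshold = -5)
    # reflect b onto forward coordinates of seq and flip strands
    b_ref <- tibble::tibble(start = L - b$end, end = L - b$start,
                            strand = ifelse(b$strand == "+", "-", "+"),
                            score = b$score)
    key <- function(x) {
      o <- order(x$start, x$strand)
      paste(x$start[o], x$end[o], x$strand[o], round(x$score[o], 9))
    }
    expect_equal(key(a), key(b_ref))
  }
})

test_that("raising the threshold never adds sites; N windows never match", {
  set.seed(3)
  pwm <- toy_pwm("CCGGA")
  seq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  thresholds <- seq(-6, pwm$max_score, length.out = 8)
  counts <- vapply(thresholds, function(th)
    nrow(scan_sequence(seq, pwm, th)), integer(1))
  expect_true(all(diff(counts) <= 0))

  # windows containing N score -Inf and are never sites
  with_n <- paste0("TT", "CCGNA", "TTTT")  # N at 0-based position 5
  hits_n <- scan_sequence(with_n, pwm, threshold = -100)
  expect_true(all(hits_n$end <= 5 | hits_n$start > 5))
  n_windows_with_n <- sum(vapply(0:(nchar(with_n) - pwm$width),
                                 function(o) o <= 5 && o + pwm$width > 5,
                                 logical(1)))
  expect_equal(nrow(hits_n),
               nrow(scan_sequence(gsub("N", "A", with_n), pwm, -100)) -
                 2L * n_windows_with_n)
  expect_error(scan_sequence("ACGTXX", pwm, 0), "invalid sequence")
})

test_that("footprint extent is centered, at least PWM width, and clipped", {
  pwm <- toy_pwm("ACGTAC")  # width 6
  seq <- paste0(strrep("T", 20), "ACGTAC", strrep("T", 20))
  h <- scan_sequence(seq, pwm, pwm$max_score - 0.5, footprint_size = 14)
  expect_equal(h$fp_end - h$fp_start, 14L)
  expect_true(h$fp_start <= h$start && h$fp_end >= h$end)
  # clipping at the construct edge
  h2 <- scan_sequence(paste0("ACGTAC", strrep("T", 20)), pwm,
                      pwm$max_score - 0.5, footprint_size = 14)
  expect_equal(h2$fp_start, 0L)
  # footprint never narrower than the PWM
  h3 <- scan_sequence(seq, pwm, pwm$max_score - 0.5, footprint_size = 4)
  expect_equal(h3$fp_end - h3$fp_start, 6L)
})

test_that("footprint recovery and false positives follow the threshold-zero rule", {
  pwm <- toy_pwm("TGACAGGT", strong = 12)
  # all-consensus footprints with flanks recover fully
  fps <- vapply(1:6, function(i) paste0("AATTC", "TGACAGGT", "GGCCA"),
                character(1))
  ev <- evaluate_pwm(pwm, fps)
  expect_equal(ev$recovery_rate, 1)
  expect_true(ev$passes)

  # negatives constructed to contain no positive-scoring window
  negs <- synthetic_negatives(synthetic_pwms("Kr")$Kr, n = 8, seed = 5)
  ev2 <- evaluate_pwm(synthetic_pwms("Kr")$Kr, fps, negs)
  expect_equal(ev2$false_positive_count, 0L)

  # exactly 7 of 10 recovered sits at the acceptance boundary (> 70% fails)
  good <- paste0("AAAAA", "TGACAGGT", "AAAAA")
  bad <- strrep("A", 18)  # scores negative everywhere
  ev3 <- evaluate_pwm(pwm, c(rep(good, 7), rep(bad, 3)))
  expect_equal(ev3$recovery_rate, 0.7)
  expect_false(ev3$passes)  # the rule requires MORE than 70%
  ev4 <- evaluate_pwm(pwm, c(rep(good, 8), rep(bad, 2)))
  expect_true(ev4$passes)
  expect_error(evaluate_pwm(pwm, character(0)), "undefined")
})

test_that("threshold_range upper bound preserves the required recovery", {
  pwm <- synthetic_pwms("Bcd")$Bcd
  fps <- synthetic_footprints(pwm, n = 10, tiers = 1:2, seed = 9)
  rng <- threshold_range(pwm, fps)
  expect_true(rng[1] == 0 && rng[2] >= rng[1])
  # at the upper bound, recovery (score strictly above) stays above 0.7
  best <- vapply(fps, function(s) {
    max(vapply(0:(nchar(s) - pwm$width), function(o)
      oracle_window_score(s, pwm, o), numeric(1)),
      vapply(0:(nchar(s) - pwm$width), function(o)
        oracle_window_score(oracle_revcomp(s), pwm, o), numeric(1)))
  }, numeric(1))
  expect_gt(mean(best > rng[2] - 1e-9), 0.7)
})

test_that("window scores agree with the Biostrings PWM scorer", {
  set.seed(21)
  pwm <- toy_pwm("TTGACA", strong = 9)
  seq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  hits <- scan_sequence(seq, pwm, threshold = -Inf)
  fwd <- hits[hits$strand == "+", ]
  m <- t(pwm$logodds)  # 4 x width, rows A,C,G,T
  ref <- Biostrings::PWMscoreStartingAt(m, Biostrings::DNAString(seq),
                                        starting.at = fwd$start + 1L)
  expect_equal(fwd$score, unname(ref), tolerance = 1e-12)
})
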