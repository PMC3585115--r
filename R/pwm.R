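#' Build a position weight matrix from base counts
#'
#' Converts a count matrix of observed bases at each position of an aligned
#' binding-site collection into a log-odds position weight matrix (PWM).
#' Each cell is regularized with a pseudocount, normalized by its column
#' total, and divided by the expected genomic frequency of the base before
#' taking logs:
#' \deqn{W_{i\beta} = \log\frac{(c_{i\beta} + p)/\sum_{\beta'}(c_{i\beta'} + p)}{b_\beta}}
#' The score of a sequence window is the sum of per-position entries and is
#' proportional to the free energy of binding.
#'
#' @param counts A numeric matrix of non-negative base counts. Accepted as
#'   either width x 4 (columns A, C, G, T) or 4 x width (rows A, C, G, T);
#'   a 4 x 4 matrix is taken as width x 4. Row/column names "A","C","G","T"
#'   disambiguate when present.
#' @param tf Name of the transcription factor the matrix belongs to.
#' @param background Expected frequencies of A, C, G, T in the genome
#'   scanned; must be strictly positive and is renormalized to sum to 1.
#'   Defaults to uniform.
#' @param pseudocount Non-negative regularizer added to every cell before
#'   normalization. Default 1.
#'
#' @return An object of class `pwm`: a list with elements `tf`, `width`,
#'   `logodds` (width x 4 matrix, columns A, C, G, T), `background`,
#'   `max_score` (score of the consensus sequence), `consensus`, and
#'   `pseudocount`.
#' @examples
#' counts <- matrix(c(8, 1, 1, 0,
#'                    0, 10, 0, 0,
#'                    2, 2, 3, 3), ncol = 4, byrow = TRUE)
#' pwm <- build_pwm(counts, tf = "toy", pseudocount = 1)
#' pwm$max_score
#' @export
build_pwm <- function(counts, tf = "TF", background = rep(0.25, 4),
                      pseudocount = 1) {
  counts <- as_counts_matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("count matrix must contain finite, non-negative values", call. = FALSE)
  }
  if (length(background) != 4 || any(!is.finite(background))) {
    stop("background must be a numeric 4-vector (A, C, G, T)", call. = FALSE)
  }
  if (any(background <= 0)) {
    stop("invalid background: all four base frequencies must be positive",
         call. = FALSE)
  }
  background <- background / sum(background)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)

  reg <- counts + pseudocount
  totals <- rowSums(reg)
  if (any(totals <= 0)) {
    stop("degenerate column: zero count total with zero pseudocount at position(s) ",
         paste(which(totals <= 0), collapse = ", "), call. = FALSE)
  }
  probs <- reg / totals
  if (any(probs == 0)) {
    stop("degenerate column: zero probability cell with zero pseudocount; ",
         "use a positive pseudocount", call. = FALSE)
  }
  logodds <- log(sweep(probs, 2, background, "/"))
  colnames(logodds) <- DNA_BASES
  rownames(logodds) <- NULL
  consensus <- paste(DNA_BASES[max.col(logodds, ties.method = "first")],
                     collapse = "")
  structure(
    list(tf = tf, width = nrow(logodds), logodds = logodds,
         background = background,
         max_score = sum(apply(logodds, 1, max)),
         consensus = consensus, pseudocount = pseudocount),
    class = "pwm"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

# Coerce a count table to width x 4 orientation with columns A,C,G,T.
as_counts_matrix <- function(counts) {
  counts <- as.matrix(counts)
  mode(counts) <- "numeric"
  has_base_rows <- !is.null(rownames(counts)) &&
    all(toupper(rownames(counts)) %in% DNA_BASES) && nrow(counts) == 4
  has_base_cols <- !is.null(colnames(counts)) &&
    all(toupper(colnames(counts)) %in% DNA_BASES) && ncol(counts) == 4
  if (has_base_rows && !has_base_cols) {
    counts <- t(counts[match(DNA_BASES, toupper(rownames(counts))), , drop = FALSE])
  } else if (has_base_cols) {
    counts <- counts[, match(DNA_BASES, toupper(colnames(counts))), drop = FALSE]
  } else if (ncol(counts) != 4 && nrow(counts) == 4) {
    counts <- t(counts)
  } else if (ncol(counts) != 4) {
    stop("count matrix must have 4 base rows or columns (A, C, G, T)",
         call. = FALSE)
  }
  colnames(counts) <- DNA_BASES
  counts
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf, ": width ", x$width,
      ", consensus ", x$consensus,
      ", max score ", format(x$max_score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert a PWM score to a relative binding affinity
#'
#' Scores are proportional to the free energy of binding; exponentiating
#' the deficit from the best attainable score gives the affinity of a site
#' relative to a perfect consensus site:
#' \deqn{K = \exp(\lambda\,(S - S_{max})) \in (0, 1]}
#' where `lambda` is the fitted proportionality constant between score and
#' free energy for this factor.
#'
#' @param score Numeric vector of window scores; each must not exceed
#'   `pwm$max_score`.
#' @param pwm A [build_pwm()] object.
#' @param lam Non-negative score-to-energy proportionality constant.
#' @return Numeric vector of relative affinities in (0, 1].
#' @export
score_to_affinity <- function(score, pwm, lam) {
  stopifnot(inherits(pwm, "pwm"))
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  if (any(score > pwm$max_score + 1e-9)) {
    stop("inconsistent score: exceeds the PWM maximum score", call. = FALSE)
  }
  exp(lam * (pmin(score, pwm$max_score) - pwm$max_score))
}

# Encode a DNA string as integers 1..4 (A,C,G,T); N and other IUPAC
# ambiguity codes become NA so that windows containing them score -Inf.
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !chars %in% c(DNA_BASES, "N", "R", "Y", "S", "W", "K", "M",
                       "B", "D", "H", "V", "U", "-")
  if (any(bad)) {
    stop("invalid sequence: non-IUPAC character(s) ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  match(chars, DNA_BASES)
}

# Reverse-complement a PWM: reverse position order and swap A<->T, C<->G.
revcomp_pwm_matrix <- function(logodds) {
  m <- logodds[rev(seq_len(nrow(logodds))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- DNA_BASES
  m
}

# Score every window of an encoded sequence against a log-odds matrix.
# Windows containing NA (ambiguous base) score -Inf.
window_scores <- function(enc, logodds) {
  w <- nrow(logodds)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (i in seq_len(w)) {
    col <- unname(logodds[i, ])[enc[i:(i + n - 1L)]]
    col[is.na(col)] <- -Inf
    scores <- scores + col
  }
  scores
}

#' Scan a sequence for binding sites on both strands
#'
#' Slides the PWM along the forward strand and its reverse complement and
#' reports every window whose score exceeds `threshold`, together with the
#' relative affinity of each site and the steric footprint it occupies.
#' Coordinates are 0-based, half-open, and always reported on the forward
#' strand; minus-strand hits are matches of the reverse-complemented motif.
#'
#' The steric footprint is the interval the bound protein physically
#' occludes. It is at least the PWM width and is widened symmetrically to
#' `footprint_size` (default 14 bp, the average footprinted Bcd site; 24 bp
#' is used for Gt) and clipped to the construct ends.
#'
#' @param seq A DNA string (A/C/G/T; windows containing N or other
#'   ambiguity codes never match).
#' @param pwm A [build_pwm()] object.
#' @param threshold Score cutoff; only windows scoring strictly above it
#'   are reported.
#' @param lam Score-to-energy constant passed to [score_to_affinity()].
#' @param footprint_size Minimum steric extent in bp. Default 14.
#'
#' @return A tibble with one row per site: `tf`, `start`, `end`, `strand`,
#'   `score`, `rel_affinity`, `fp_start`, `fp_end`, `center`, sorted by
#'   `start` then strand.
#' @export
scan_sequence <- function(seq, pwm, threshold, lam = 1, footprint_size = 14) {
  stopifnot(inherits(pwm, "pwm"))
  enc <- encode_dna(seq)
  L <- length(enc)
  w <- pwm$width
  if (L < w) return(empty_sites())

  fwd <- window_scores(enc, pwm$logodds)
  rvs <- window_scores(enc, revcomp_pwm_matrix(pwm$logodds))

  hit_f <- which(fwd > threshold)
  hit_r <- which(rvs > threshold)
  sites <- tibble::tibble(
    tf = pwm$tf,
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + w,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rvs[hit_r])
  )
  sites$rel_affinity <- score_to_affinity(sites$score, pwm, lam)
  ext <- max(0L, as.integer(footprint_size) - w)
  sites$fp_start <- pmax(0L, sites$start - ext %/% 2L)
  sites$fp_end <- pmin(L, sites$end + (ext - ext %/% 2L))
  sites$center <- (sites$start + sites$end) / 2
  dplyr::arrange(sites, .data$start, .data$strand)
}

empty_sites <- function() {
  tibble::tibble(tf = character(), start = integer(), end = integer(),
                 strand = character(), score = numeric(),
                 rel_affinity = numeric(), fp_start = integer(),
                 fp_end = integer(), center = numeric())
}

#' Evaluate a PWM against known footprints and negative sequences
#'
#' Applies the selection rule used when choosing among candidate matrices:
#' with the score threshold set to zero, a known footprint counts as
#' recovered when the best score over the footprint sequence extended by 5
#' bp of flanking sequence on each side (both strands) is positive, and a
#' negative control sequence counts as a false positive when any of its
#' windows scores above zero. Matrices failing to recover more than 70% of
#' footprints are discarded; among the survivors the one with the fewest
#' false positives is preferred.
#'
#' @param pwm A [build_pwm()] object.
#' @param footprints Character vector of footprint sequences, each already
#'   including its flanking context.
#' @param negatives Character vector of negative-control sequences
#'   (typically 20 bp segments with no binding evidence).
#' @return A list with `recovery_rate` (fraction of footprints recovered),
#'   `false_positive_count`, and `passes` (recovery_rate > 0.7).
#' @export
evaluate_pwm <- function(pwm, footprints, negatives = character()) {
  stopifnot(inherits(pwm, "pwm"))
  if (length(footprints) == 0) {
    stop("undefined recovery: empty footprint list", call. = FALSE)
  }
  best_score <- function(s) {
    enc <- encode_dna(s)
    if (length(enc) < pwm$width) return(-Inf)
    max(window_scores(enc, pwm$logodds),
        window_scores(enc, revcomp_pwm_matrix(pwm$logodds)))
  }
  recovered <- vapply(footprints, function(s) best_score(s) > 0, logical(1))
  fp <- if (length(negatives)) {
    sum(vapply(negatives, function(s) best_score(s) > 0, logical(1)))
  } else 0L
  rate <- mean(recovered)
  list(recovery_rate = rate, false_positive_count = as.integer(fp),
       passes = rate > 0.7)
}

#' Score-threshold range compatible with footprint recovery
#'
#' Returns the interval of thresholds for which the PWM still recovers more
#' than the required fraction of known footprints: the lower end is 0 (the
#' evaluation threshold) and the upper end is the largest threshold at
#' which recovery stays above `min_recovery`. Used to bound free threshold
#' parameters during fitting.
#'
#' @inheritParams evaluate_pwm
#' @param min_recovery Required recovered fraction (default 0.7).
#' @return Numeric `c(lo, hi)`.
#' @export
threshold_range <- function(pwm, footprints, min_recovery = 0.7) {
  best <- vapply(footprints, function(s) {
    enc <- encode_dna(s)
    if (length(enc) < pwm$width) return(-Inf)
    max(window_scores(enc, pwm$logodds),
        window_scores(enc, revcomp_pwm_matrix(pwm$logodds)))
  }, numeric(1))
  best <- sort(best, decreasing = TRUE)
  need <- floor(min_recovery * length(best)) + 1L
  hi <- if (need <= length(best)) best[need] else best[length(best)]
  c(0, max(0, hi))
}
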