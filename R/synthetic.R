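#' Synthetic-data specification
#'
#' Declares the study conditions the generator emulates: a grid of nuclear
#' positions spanning 35-92% egg length (58 positions at 1% spacing, the
#' interval over which the nine-factor dataset covers all essential
#' regulators), smooth concentration profiles for the default roster (an
#' anterior Bcd-like exponential gradient, a posterior Cad-like gradient,
#' two broad activator domains, bell-shaped gap-gene repressor domains and
#' a dual-domain Hb-like profile), and multiplicative observation noise
#' with relative standard deviation 0.075 — inside the 5-10% accuracy of
#' the quantitative expression data the model was designed for.
#'
#' @param n_positions Number of anterior-posterior grid points.
#' @param ap_range Two-vector, % egg length endpoints of the grid.
#' @param noise_sd Relative standard deviation of multiplicative
#'   observation noise.
#' @param seed Integer seed; fully determines generator output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positions = 58, ap_range = c(35, 92),
                           noise_sd = 0.075, seed = 1) {
  if (n_positions < 2 || diff(ap_range) <= 0) {
    stop("invalid spec: need an increasing grid of at least 2 positions",
         call. = FALSE)
  }
  structure(list(n_positions = n_positions, ap_range = ap_range,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

# Fixed consensus motifs of the toy PWMs, one per roster factor. Chosen
# distinct so cross-factor matches are rare at working thresholds.
SYNTH_CONSENSUS <- c(
  Bcd = "TAATCCCAAT", Cad = "TTTATGGCCG", Dst = "TTCCCGGAAG",
  Dic = "AACAATGGCA", Kr = "AACGGGTTAG", Kni = "GACTAGACCT",
  Gt = "TTACGTACGA", Tll = "AAGTCAAGGC", Hb = "CATAAAAACG"
)

#' Toy position weight matrices for the synthetic roster
#'
#' One 10-column PWM per factor, built from a count table with 20
#' observations of the consensus base and none of the others at every
#' position (pseudocount 0.5), giving a per-position log-odds gap of about
#' 3.7 between consensus and mismatch. Planted sites with 0, 1, 2
#' mismatches then occupy well-separated affinity tiers, and random
#' background sequence rarely scores above the default working threshold.
#'
#' @param tfs Which factors to build (default: the full roster).
#' @param background Genomic base frequencies.
#' @return Named list of [build_pwm()] objects.
#' @export
synthetic_pwms <- function(tfs = names(SYNTH_CONSENSUS),
                           background = rep(0.25, 4)) {
  pwms <- lapply(tfs, function(tf) {
    cons <- strsplit(SYNTH_CONSENSUS[[tf]], "")[[1]]
    counts <- matrix(0, length(cons), 4, dimnames = list(NULL, DNA_BASES))
    counts[cbind(seq_along(cons), match(cons, DNA_BASES))] <- 20
    build_pwm(counts, tf = tf, background = background, pseudocount = 0.5)
  })
  stats::setNames(pwms, tfs)
}

#' Generate smooth transcription-factor concentration profiles
#'
#' Deterministic given the spec: profile shapes are fixed functions of
#' position (exponential gradients and Gaussian bumps in relative
#' fluorescence units, maximum about 1), emulating averaged,
#' background-removed protein data. Observation noise is applied later, to
#' simulated reporter expression, not to these inputs.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with `position` and one column per factor.
#' @export
generate_profiles <- function(spec = synthetic_spec()) {
  x <- seq(spec$ap_range[1], spec$ap_range[2],
           length.out = spec$n_positions)
  bump <- function(center, width, amp = 1) amp * exp(-((x - center) / width)^2)
  tibble::tibble(
    position = x,
    Bcd = exp(-(x - spec$ap_range[1]) / 15),
    Cad = exp(-(spec$ap_range[2] - x) / 18),
    Dst = 0.4 + bump(64, 22, 0.6),
    Dic = 0.5 + bump(55, 30, 0.5),
    Kr = bump(59, 7),
    Kni = bump(70, 5.5),
    Gt = bump(78, 5) + bump(40, 6, 0.6),
    Tll = 1 / (1 + exp(-(x - 86) / 2)),
    Hb = 1 / (1 + exp((x - 48) / 2.5)) + bump(84, 4.5, 0.7)
  )
}

# Apply t-1 mismatches to a consensus (tier 1 = perfect). Mismatched
# positions are taken from the 5' end; each offending base is advanced
# cyclically so the change is deterministic.
tier_motif <- function(consensus, tier) {
  chars <- strsplit(consensus, "")[[1]]
  n_mm <- tier - 1L
  if (n_mm > 0) {
    for (i in seq_len(min(n_mm, length(chars)))) {
      chars[i] <- DNA_BASES[match(chars[i], DNA_BASES) %% 4L + 1L]
    }
  }
  paste(chars, collapse = "")
}

#' Generate a construct with a planted binding-site architecture
#'
#' Draws a random background sequence at the given base composition and
#' overwrites it with near-consensus motifs at declared offsets. Affinity
#' tiers are realized by controlled mismatch counts (tier 1 = consensus,
#' tier t = t-1 mismatches), so planted sites occupy known rungs of the
#' affinity ordering.
#'
#' @param architecture Tibble with columns `tf`, `offset` (0-based), and
#'   optionally `tier` (default 1) and `strand` (default "+").
#' @param length Construct length in bp.
#' @param tss TSS coordinate (default `length - 1`: regulatory sequence 5'
#'   of the TSS).
#' @param seed Integer seed for the background sequence.
#' @param background Base composition of the background.
#' @param allow_overlap Permit planted motifs to overlap.
#' @param id Construct identifier.
#' @param targeted Whether the construct sits at the targeted landing site
#'   (position-effect scale fixed at 1).
#' @return A list of class `planted_construct`: `construct` (id), `seq`,
#'   `tss`, `targeted`, `planted` (the architecture).
#' @export
generate_construct <- function(architecture, length = 1000,
                               tss = length - 1, seed = 1,
                               background = rep(0.25, 4),
                               allow_overlap = FALSE, id = "synthetic",
                               targeted = TRUE) {
  architecture <- tibble::as_tibble(architecture)
  if (!"tier" %in% names(architecture)) architecture$tier <- 1L
  if (!"strand" %in% names(architecture)) architecture$strand <- "+"
  motifs <- vapply(seq_len(nrow(architecture)), function(i) {
    m <- tier_motif(SYNTH_CONSENSUS[[architecture$tf[i]]],
                    architecture$tier[i])
    if (architecture$strand[i] == "-") revcomp_string(m) else m
  }, character(1))
  ends <- architecture$offset + nchar(motifs)
  if (any(ends > length) || any(architecture$offset < 0)) {
    stop("layout error: planted motif extends outside the construct",
         call. = FALSE)
  }
  if (!allow_overlap && nrow(architecture) > 1) {
    ord <- order(architecture$offset)
    if (any(architecture$offset[ord][-1] < ends[ord][-nrow(architecture)])) {
      stop("layout error: planted motifs collide; pass allow_overlap = TRUE ",
           "to permit this", call. = FALSE)
    }
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  chars <- sample(DNA_BASES, length, replace = TRUE,
                  prob = background / sum(background))
  for (i in seq_len(nrow(architecture))) {
    idx <- architecture$offset[i] + seq_len(nchar(motifs[i]))
    chars[idx] <- strsplit(motifs[i], "")[[1]]
  }
  structure(list(construct = id, seq = paste(chars, collapse = ""),
                 tss = tss, targeted = targeted, planted = architecture),
            class = "planted_construct")
}

revcomp_string <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Seed handling that restores the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Excise a spacer interval from a planted construct
#'
#' Removes `[start, start + length)` from the sequence; planted motifs and
#' the TSS downstream of the cut shift left by exactly `length` bp,
#' emulating enhancer-fusion variants with and without spacer DNA.
#'
#' @param construct A [generate_construct()] object.
#' @param start 0-based start of the excised interval.
#' @param length Length of the excised interval in bp.
#' @param id Id for the derived construct.
#' @return A new `planted_construct`.
#' @export
excise_spacer <- function(construct, start, length,
                          id = paste0(construct$construct, "_fused")) {
  seq <- construct$seq
  L <- nchar(seq)
  stopifnot(start >= 0, start + length <= L)
  planted <- construct$planted
  if (any(planted$offset >= start & planted$offset < start + length)) {
    stop("layout error: excision removes a planted site", call. = FALSE)
  }
  newseq <- paste0(substr(seq, 1, start),
                   substr(seq, start + length + 1, L))
  shift <- ifelse(planted$offset >= start + length, length, 0L)
  planted$offset <- planted$offset - shift
  tss <- construct$tss - if (construct$tss >= start + length) length else 0L
  structure(list(construct = id, seq = newseq, tss = tss,
                 targeted = construct$targeted, planted = planted),
            class = "planted_construct")
}

#' Default seven-construct synthetic panel
#'
#' Two enhancer blocks are laid out in the spirit of the fusion
#' experiments the model was trained on: a proximal block with
#' cooperative-activator (Bcd-like), repressor and broad-activator sites,
#' and a distal block carrying coactivation-target (Hb-like) and posterior
#' repressor sites. Four targeted constructs place the two blocks with and
#' without 172 bp and 360 bp spacers in both orders; three additional
#' non-targeted constructs (single blocks and a long fragment) each carry
#' a free position-effect scale.
#'
#' @param seed Integer seed for background sequence.
#' @return Named list of seven `planted_construct` objects.
#' @export
default_constructs <- function(seed = 1) {
  # distal (MSE3-like) block laid 5' of the proximal (MSE2-like) block;
  # the 3'-most Hb site sits close enough to the block edge that excising
  # the spacer brings it within Bcd coactivation range of the proximal
  # block, reproducing the fusion constructs' recruitment geometry
  block3 <- tibble::tibble(
    tf = c("Dst", "Kni", "Hb", "Cad", "Kni", "Tll", "Hb"),
    offset = c(10, 60, 120, 170, 230, 290, 350),
    tier = c(1, 1, 1, 1, 2, 2, 1)
  )
  block2 <- tibble::tibble(
    tf = c("Gt", "Bcd", "Bcd", "Kr", "Dst", "Kr", "Bcd", "Hb", "Kr"),
    offset = c(0, 40, 90, 140, 190, 240, 290, 330, 380),
    tier = c(1, 1, 2, 1, 1, 2, 2, 2, 1)
  )
  shift <- function(arch, by) dplyr::mutate(arch, offset = .data$offset + by)
  make <- function(id, arch, len, seed_off, targeted = TRUE) {
    generate_construct(arch, length = len, tss = len - 20,
                       seed = seed + seed_off, id = id, targeted = targeted)
  }
  b3len <- 410
  spacer <- 172
  list(
    M3_2 = make("M3_2", dplyr::bind_rows(block3,
                                         shift(block2, b3len + spacer)),
                b3len + spacer + 440, 1),
    M32 = make("M32", dplyr::bind_rows(block3, shift(block2, b3len)),
               b3len + 440, 2),
    M2_3 = make("M2_3", dplyr::bind_rows(block2,
                                         shift(block3, 420 + 360)),
                420 + 360 + b3len + 60, 3),
    M23 = make("M23", dplyr::bind_rows(block2, shift(block3, 420)),
               420 + b3len + 60, 4),
    MSE2 = make("MSE2", block2, 470, 5, targeted = FALSE),
    MSE3 = make("MSE3", block3, 450, 6, targeted = FALSE),
    C1700 = make("C1700",
                 dplyr::bind_rows(block3, shift(block2, b3len + 300)),
                 b3len + 300 + 470, 7, targeted = FALSE)
  )
}

#' Small construct panel for parameter-recovery studies
#'
#' Four compact constructs (5-6 planted sites each) whose geometries
#' separate the model's mechanisms so that a reduced free-parameter set is
#' locally identifiable: a cooperative activator pair with an interleaved
#' short-range quencher; an activator/coactivation-target pair out of
#' quenching reach; an activator pair with a quencher parked at the TSS
#' (direct repression only); and a mixed construct. Together with the
#' default concentration profiles these give informative, non-degenerate
#' training data for recovery tests of concentration scales, recruiting
#' strengths and interaction efficiencies.
#'
#' @param seed Integer seed for background sequence.
#' @return Named list of four `planted_construct` objects.
#' @export
recovery_panel <- function(seed = 1) {
  arch <- list(
    R1 = tibble::tibble(
      tf = c("Bcd", "Kr", "Bcd", "Dst"),
      offset = c(40, 80, 120, 300),
      tier = c(1, 1, 2, 1)
    ),
    R2 = tibble::tibble(
      tf = c("Bcd", "Hb", "Dst", "Kni"),
      offset = c(60, 140, 260, 380),
      tier = c(1, 1, 1, 1)
    ),
    R3 = tibble::tibble(
      tf = c("Bcd", "Bcd", "Dst", "Kr"),
      offset = c(30, 80, 200, 420),
      tier = c(1, 2, 1, 1)
    ),
    R4 = tibble::tibble(
      tf = c("Hb", "Bcd", "Kr", "Dst", "Cad"),
      offset = c(20, 100, 160, 240, 330),
      tier = c(1, 1, 2, 1, 1)
    )
  )
  lens <- c(R1 = 480, R2 = 460, R3 = 470, R4 = 450)
  out <- lapply(names(arch), function(id) {
    generate_construct(arch[[id]], length = lens[[id]],
                       tss = lens[[id]] - 20,
                       seed = seed + match(id, names(arch)), id = id)
  })
  stats::setNames(out, names(arch))
}

#' Simulate a training dataset by forward prediction plus noise
#'
#' Runs the full model with `true_params` on every construct and position,
#' then perturbs each prediction with multiplicative Gaussian noise,
#' clipped at zero:
#' \eqn{y = \max(0, \hat{y}\,(1 + \varepsilon))},
#' \eqn{\varepsilon \sim N(0, \sigma_{rel}^2)}. The generating parameters
#' are recorded alongside the observations for recovery tests.
#'
#' @param constructs List of `planted_construct` objects (or any lists
#'   with `construct`, `seq`, `tss`, `targeted`).
#' @param profiles Concentration tibble from [generate_profiles()].
#' @param true_params Generating parameter tibble.
#' @param pwms Named list of PWMs.
#' @param noise_sd Relative noise standard deviation (0 disables noise).
#' @param seed Integer seed for the noise draws.
#' @param config Model configuration.
#' @return A list of class `training_set`: `constructs` (tibble),
#'   `profiles`, `observations` (`construct`, `position`, `observed`),
#'   `noiseless`, `true_params`, `noise_sd`, `seed`.
#' @export
simulate_dataset <- function(constructs, profiles, true_params, pwms,
                             noise_sd = 0.075, seed = 1,
                             config = default_model_config()) {
  preds <- purrr::map_dfr(constructs, function(con) {
    predict_profile(con, pwms, profiles, true_params, config)
  })
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  eps <- stats::rnorm(nrow(preds), 0, noise_sd)
  obs <- tibble::tibble(
    construct = preds$construct,
    position = preds$position,
    observed = pmax(0, preds$rate * (1 + eps))
  )
  ctab <- purrr::map_dfr(constructs, function(con) {
    tibble::tibble(construct = con$construct, seq = con$seq, tss = con$tss,
                   targeted = isTRUE(con$targeted))
  })
  structure(list(constructs = ctab, profiles = profiles, observations = obs,
                 noiseless = tibble::as_tibble(preds),
                 true_params = true_params, noise_sd = noise_sd, seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> ", nrow(x$constructs), " constructs x ",
      nrow(x$profiles), " positions = ", nrow(x$observations),
      " observations (relative noise sd ", x$noise_sd, ")\n", sep = "")
  invisible(x)
}

#' Footprint and negative-control sequences for PWM evaluation
#'
#' `synthetic_footprints()` draws near-consensus sites (mismatch count
#' sampled from `tiers`) embedded in `flank` bp of random sequence on each
#' side, emulating footprinted binding sites with genomic context.
#' `synthetic_negatives()` draws fixed-length sequences and keeps only
#' those in which no window on either strand scores above zero, emulating
#' unbound control segments.
#'
#' @param pwm A [build_pwm()] object for a roster factor.
#' @param n Number of sequences.
#' @param flank Flank length (bp) for footprints.
#' @param tiers Mismatch tiers to sample from (see [generate_construct()]).
#' @param len Negative sequence length.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
synthetic_footprints <- function(pwm, n = 10, flank = 5, tiers = 1:2,
                                 seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cons <- SYNTH_CONSENSUS[[pwm$tf]]
  vapply(seq_len(n), function(i) {
    core <- tier_motif(cons, sample(tiers, 1))
    paste0(paste(sample(DNA_BASES, flank, TRUE), collapse = ""), core,
           paste(sample(DNA_BASES, flank, TRUE), collapse = ""))
  }, character(1))
}

#' @rdname synthetic_footprints
#' @export
synthetic_negatives <- function(pwm, n = 15, len = 20, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  out <- character(0)
  tries <- 0
  while (length(out) < n && tries < 10000) {
    tries <- tries + 1
    s <- paste(sample(DNA_BASES, len, TRUE), collapse = "")
    enc <- encode_dna(s)
    best <- max(window_scores(enc, pwm$logodds),
                window_scores(enc, revcomp_pwm_matrix(pwm$logodds)))
    if (best <= 0) out <- c(out, s)
  }
  if (length(out) < n) {
    stop("could not draw enough negative sequences below threshold",
         call. = FALSE)
  }
  out
}
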