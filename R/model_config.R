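#' Default model configuration: the nine-factor blastoderm roster
#'
#' Declares the transcription factors the model knows about, their
#' regulatory roles, steric footprint sizes, and the interaction wiring:
#' the activators are Bcd, Cad, D-STAT (Dst) and Dichaete (Dic); the
#' repressors are Kr, Kni, Gt, Tll and Hb. Hb is a coactivation target —
#' DNA-bound Hb is converted from quencher to activator by Bcd or Cad
#' bound nearby — and Bcd binds cooperatively in pairs assigned within a
#' 60 bp range. Binding sites occlude at least 14 bp (the average
#' footprinted Bcd site); Gt occludes 24 bp.
#'
#' The construct manifest lists four enhancer-fusion reporters integrated
#' at a common targeted landing site (no position effect, scale fixed at 1)
#' and three reporters at other insertion sites, each of which carries one
#' free position-effect scale.
#'
#' @param tfs Optional replacement TF roster tibble with columns `tf`,
#'   `role`, `footprint`, `cooperative`, `coact_target`, `threshold_fixed`.
#' @param constructs Optional replacement construct manifest tibble with
#'   columns `construct`, `targeted`.
#' @return An object of class `model_config`.
#' @export
default_model_config <- function(tfs = NULL, constructs = NULL) {
  if (is.null(tfs)) {
    tfs <- tibble::tibble(
      tf = c("Bcd", "Cad", "Dst", "Dic", "Kr", "Kni", "Gt", "Tll", "Hb"),
      role = c(rep("activator", 4), rep("repressor", 5)),
      footprint = c(14, 14, 14, 14, 14, 14, 24, 14, 14),
      cooperative = c(TRUE, rep(FALSE, 8)),
      coact_target = c(rep(FALSE, 8), TRUE),
      threshold_fixed = c(TRUE, rep(FALSE, 7), TRUE)
    )
  }
  if (is.null(constructs)) {
    constructs <- tibble::tibble(
      construct = c("M3_2", "M32", "M2_3", "M23", "MSE2", "MSE3", "C1700"),
      targeted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    )
  }
  stopifnot(all(tfs$role %in% c("activator", "repressor")))
  if (any(tfs$coact_target & tfs$role != "repressor")) {
    stop("a coactivation target must have role 'repressor' (quencher)",
         call. = FALSE)
  }
  structure(
    list(
      tfs = tfs,
      coactivation = tibble::tibble(
        coactivator = c("Bcd", "Cad"),
        target = c("Hb", "Hb")
      ),
      constructs = constructs,
      coop_range_bp = 60,
      quench_r_full = 100,
      quench_r_zero = 150,
      coact_offset_bp = 20,
      enumeration_cap = 20,
      ap_range = c(35, 92),
      n_positions = 58
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", nrow(x$tfs), " TFs (",
      sum(x$tfs$role == "activator"), " activators, ",
      sum(x$tfs$role == "repressor"), " repressors), ",
      nrow(x$constructs), " constructs\n", sep = "")
  invisible(x)
}

#' Default free-parameter table for a model configuration
#'
#' Builds the complete parameter vector as a tibble with bounds and
#' fixed/free flags. Under the default nine-factor, seven-construct
#' configuration the free entries are:
#' per TF a concentration scale `D` and a score-to-energy constant
#' `lambda`; per activator an adapter-recruiting strength `alpha`; per
#' repressor quenching and direct-repression efficiencies `beta_q` and
#' `beta_d`; the Bcd cooperativity weight `omega`; per coactivator a
#' coactivation efficiency `beta_co` and range `coact_range`; the
#' recruiting strength `alpha_coact` of the coactivated target; the
#' activation energy barrier `theta`; one PWM score `threshold` per TF
#' whose threshold is not pinned by independent binding data (all but Bcd
#' and Hb); and one `pos_effect` scale per non-targeted construct. This
#' totals 49 free parameters, of which 10 are position-effect and
#' threshold parameters. The saturating rate `R_max` is fixed.
#'
#' Bounds: efficiencies in \[0, 1\]; the Bcd coactivation range is
#' constrained to \[150, 200\] bp and the Cad range to \[10, 200\] bp by
#' independent experimental criteria; `D` and `R_max` are searched on a
#' log scale.
#'
#' @param config A [default_model_config()] object.
#' @return A tibble with columns `param`, `tf` (TF name, construct id, or
#'   NA for globals), `value`, `lower`, `upper`, `free`, `scale`.
#' @export
default_params <- function(config = default_model_config()) {
  tfs <- config$tfs
  act <- tfs$tf[tfs$role == "activator"]
  rep_ <- tfs$tf[tfs$role == "repressor"]
  coop <- tfs$tf[tfs$cooperative]
  targets <- tfs$tf[tfs$coact_target]

  row <- function(param, tf, value, lower, upper, free, scale = "linear") {
    tibble::tibble(param = param, tf = tf, value = value, lower = lower,
                   upper = upper, free = free, scale = scale)
  }
  coact <- config$coactivation
  coact_lo <- ifelse(coact$coactivator == "Bcd", 150, 10)
  coact_hi <- 200

  params <- dplyr::bind_rows(
    row("D", tfs$tf, 3, 1e-3, 1e3, TRUE, "log"),
    row("lambda", tfs$tf, 0.4, 0.01, 2, TRUE),
    row("alpha", act, 4, 0, 30, TRUE),
    row("beta_q", rep_, 0.8, 0, 1, TRUE),
    row("beta_d", rep_, 0.8, 0, 1, TRUE),
    if (length(coop)) row("omega", coop, 5, 1, 30, TRUE),
    row("beta_co", coact$coactivator, 0.8, 0, 1, TRUE),
    row("coact_range", coact$coactivator,
        ifelse(coact$coactivator == "Bcd", 165, 50), coact_lo,
        coact_hi, TRUE),
    if (length(targets)) row("alpha_coact", targets, 4, 0, 30, TRUE),
    row("theta", NA_character_, 10, 0, 30, TRUE),
    row("R_max", NA_character_, 100, 1, 1e4, FALSE, "log"),
    row("threshold", tfs$tf, 8, 0, 12, !tfs$threshold_fixed),
    row("pos_effect", config$constructs$construct,
        1, 0.1, 10, !config$constructs$targeted)
  )
  class(params) <- c("model_params", class(params))
  params
}

#' Count free parameters
#'
#' @param params A parameter tibble from [default_params()].
#' @param subset Optional character vector of parameter names to restrict
#'   the count to (e.g. `c("pos_effect", "threshold")`).
#' @return Integer count of entries flagged free.
#' @examples
#' p <- default_params()
#' count_free_parameters(p)                                # 49
#' count_free_parameters(p, c("pos_effect", "threshold"))  # 10
#' @export
count_free_parameters <- function(params, subset = NULL) {
  check_params(params)
  if (!is.null(subset)) params <- params[params$param %in% subset, ]
  sum(params$free)
}

check_params <- function(params) {
  need <- c("param", "tf", "value", "lower", "upper", "free")
  if (!all(need %in% names(params))) {
    stop("invalid config: parameter table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(params$lower > params$upper)) {
    stop("invalid config: lower bound exceeds upper bound for ",
         paste(params$param[params$lower > params$upper], collapse = ", "),
         call. = FALSE)
  }
  invisible(params)
}

#' Look up a parameter value
#'
#' @param params Parameter tibble.
#' @param param Parameter name.
#' @param tf TF name, construct id, or NA for globals.
#' @param default Value returned when the entry is absent (default: error).
#' @return The scalar value.
#' @export
param_value <- function(params, param, tf = NA_character_, default = NULL) {
  hit <- params$param == param &
    (is.na(tf) & is.na(params$tf) | !is.na(params$tf) & params$tf %in% tf)
  if (!any(hit)) {
    if (!is.null(default)) return(default)
    stop("parameter not found: ", param, if (!is.na(tf)) paste0("[", tf, "]"),
         call. = FALSE)
  }
  params$value[which(hit)[1]]
}

#' Set parameter values
#'
#' @inheritParams param_value
#' @param value Replacement value(s), recycled over matching rows.
#' @return The modified parameter tibble.
#' @export
set_param <- function(params, param, value, tf = NULL) {
  hit <- params$param == param
  if (!is.null(tf)) hit <- hit & !is.na(params$tf) & params$tf %in% tf
  if (!any(hit)) stop("parameter not found: ", param, call. = FALSE)
  params$value[hit] <- value
  params
}

# Named vector of one parameter across TFs, e.g. all D values.
param_by_tf <- function(params, param) {
  rows <- params[params$param == param & !is.na(params$tf), ]
  stats::setNames(rows$value, rows$tf)
}

# Flatten the parameter tibble into named lookup vectors once per
# evaluation; the tibble accessors are too slow for the fitting hot path.
param_tables <- function(params) {
  pp <- params$param
  tf <- params$tf
  val <- params$value
  pick <- function(name) {
    i <- which(pp == name)
    stats::setNames(val[i], tf[i])
  }
  scalar <- function(name, default = NA_real_) {
    i <- which(pp == name)
    if (length(i)) val[i[1]] else default
  }
  list(D = pick("D"), lambda = pick("lambda"), alpha = pick("alpha"),
       alpha_coact = pick("alpha_coact"), beta_q = pick("beta_q"),
       beta_d = pick("beta_d"), beta_co = pick("beta_co"),
       coact_range = pick("coact_range"), pos_effect = pick("pos_effect"),
       threshold = pick("threshold"),
       omega = scalar("omega", 1), theta = scalar("theta"),
       R_max = scalar("R_max"))
}

# Named lookup with 0 default for factors without the parameter.
lk0 <- function(table, keys) {
  out <- unname(table[keys])
  out[is.na(out)] <- 0
  out
}
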