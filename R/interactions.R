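#' Bounded distance-response function
#'
#' The range over which a protein-protein mechanism (coactivation,
#' quenching, direct repression) acts is modeled by a trapezoidal function
#' of the center-to-center distance between sites: 1 up to `r_full`, 0 at
#' and beyond `r_zero`, linear in between. Setting `r_full == r_zero`
#' gives a hard step.
#'
#' @param d Distance(s) in bp, >= 0.
#' @param r_full Distance up to which the mechanism acts at full strength.
#' @param r_zero Distance at and beyond which it has no effect.
#' @return Values in \[0, 1\], non-increasing in `d`.
#' @examples
#' range_value(c(0, 170, 200), r_full = 160, r_zero = 180)
#' @export
range_value <- function(d, r_full, r_zero) {
  if (r_full < 0 || r_zero < r_full) {
    stop("require 0 <= r_full <= r_zero", call. = FALSE)
  }
  if (r_zero == r_full) return(as.numeric(d <= r_full))
  pmin(1, pmax(0, (r_zero - d) / (r_zero - r_full)))
}

# Role of each site's TF under a configuration.
site_roles <- function(sites, config) {
  role <- config$tfs$role[match(sites$tf, config$tfs$tf)]
  if (any(is.na(role))) {
    stop("TF without a declared role: ",
         paste(unique(sites$tf[is.na(role)]), collapse = ", "), call. = FALSE)
  }
  role
}

# Split physical occupancy (n_sites x n_pos matrix) into activator-acting
# and quencher-acting components via coactivation. Returns list(f_act,
# f_quench); rows sum to f_phys for every site. `pt` is a param_tables()
# lookup list.
coactivation_matrix <- function(sites, f_phys, pt, config) {
  n <- nrow(sites)
  npos <- ncol(f_phys)
  tf <- sites$tf
  center <- sites$center
  role <- site_roles(sites, config)
  is_target <- config$tfs$coact_target[match(tf, config$tfs$tf)]
  f_act <- matrix(0, n, npos)
  f_quench <- matrix(0, n, npos)
  f_act[role == "activator", ] <- f_phys[role == "activator", , drop = FALSE]
  f_quench[role == "repressor", ] <- f_phys[role == "repressor", , drop = FALSE]

  if (any(pt$beta_co < 0 | pt$beta_co > 1, na.rm = TRUE)) {
    stop("invalid efficiency: beta_co must lie in [0, 1]", call. = FALSE)
  }
  for (i in which(is_target)) {
    coactivators <- config$coactivation$coactivator[
      config$coactivation$target == tf[i]]
    surv <- rep(1, npos)
    for (co in coactivators) {
      beta <- lk0(pt$beta_co, co)
      if (beta == 0) next
      r <- lk0(pt$coact_range, co)
      js <- which(tf == co & seq_len(n) != i)
      if (!length(js)) next
      rv <- range_value(abs(center[js] - center[i]),
                        r, r + config$coact_offset_bp)
      for (k in which(rv > 0)) {
        surv <- surv * (1 - beta * f_phys[js[k], ] * rv[k])
      }
    }
    converted <- 1 - surv
    f_act[i, ] <- f_phys[i, ] * converted
    f_quench[i, ] <- f_phys[i, ] - f_act[i, ]
  }
  list(f_act = f_act, f_quench = f_quench)
}

# Pairwise quenching range values (center-to-center), zero on the
# diagonal so dual-role sites never quench themselves.
quench_range_matrix <- function(center, config) {
  d <- abs(outer(center, center, "-"))
  rv <- range_value(d, config$quench_r_full, config$quench_r_zero)
  dim(rv) <- dim(d)
  diag(rv) <- 0
  rv
}

# Attenuate activator-acting occupancies by nearby quencher-acting
# occupancies (short-range repression). Survival-product form: each
# quencher within range multiplies the activator by
# (1 - beta_q * f_quench * range). Self-quenching of a dual-role site is
# excluded. Returns the quenched activator matrix.
quenching_matrix <- function(sites, f_act, f_quench, pt, config,
                             rv_q = NULL) {
  n <- nrow(sites)
  f_act_q <- f_act
  beta_q <- lk0(pt$beta_q, sites$tf)
  if (any(beta_q < 0 | beta_q > 1)) {
    stop("invalid efficiency: beta_q must lie in [0, 1]", call. = FALSE)
  }
  rv_q <- rv_q %||% quench_range_matrix(sites$center, config)
  quenchers <- which(beta_q > 0 & rowSums(f_quench) > 0)
  actors <- which(rowSums(f_act) > 0)
  for (i in actors) {
    surv <- rep(1, ncol(f_act))
    for (j in quenchers) {
      rv <- rv_q[i, j]
      if (rv > 0) surv <- surv * (1 - beta_q[j] * f_quench[j, ] * rv)
    }
    f_act_q[i, ] <- f_act[i, ] * surv
  }
  f_act_q
}

#' Split physical occupancies into activator- and quencher-acting parts
#'
#' Implements coactivation: a DNA-bound repressor that is a coactivation
#' target (Hb) is converted into an activator by coactivator sites (Bcd,
#' Cad) bound nearby. For target site \eqn{i} the converted fraction is
#' \deqn{C_i = 1 - \prod_j \bigl(1 - \beta_{co}(j)\, f_j \, r(d_{ij})\bigr)}
#' over coactivator sites \eqn{j}, and \eqn{f^A_i = f_i C_i},
#' \eqn{f^Q_i = f_i - f^A_i}: the activating and repressing activities sum
#' to the physical occupancy exactly. Plain activators act fully as
#' activators and plain repressors fully as quenchers.
#'
#' @param occ Long occupancy tibble from [occupancy_landscape()]
#'   (`position`, `site_id`, `f`).
#' @param sites The site tibble the landscape was computed from.
#' @param params Parameter tibble (`beta_co`, `coact_range` per
#'   coactivator).
#' @param config Model configuration (roles, coactivation wiring, range
#'   offset).
#' @return `occ` with columns `f_phys`, `f_act`, `f_quench` added.
#' @export
apply_coactivation <- function(occ, sites, params,
                               config = default_model_config()) {
  sites <- ensure_site_id(sites)
  fm <- occ_to_matrix(occ, sites)
  co <- coactivation_matrix(sites, fm$f, param_tables(params), config)
  occ <- dplyr::arrange(occ, .data$position,
                        match(.data$site_id, sites$site_id))
  occ$f_phys <- as.vector(fm$f)
  occ$f_act <- as.vector(co$f_act)
  occ$f_quench <- as.vector(co$f_quench)
  occ
}

#' Apply short-range quenching to activator-acting occupancies
#'
#' Each functionally active activator is attenuated by every
#' quencher-acting site bound within quenching range (~150 bp):
#' \deqn{f^{AQ}_i = f^A_i \prod_j \bigl(1 - \beta_Q(j)\, f^Q_j\,
#' r(d_{ij})\bigr)}
#' Distances are center-to-center; sites beyond the range function's zero
#' point have exactly no influence.
#'
#' @param func Functional occupancy tibble from [apply_coactivation()].
#' @inheritParams apply_coactivation
#' @return `func` with an `f_act_quenched` column added.
#' @export
apply_quenching <- function(func, sites, params,
                            config = default_model_config()) {
  sites <- ensure_site_id(sites)
  npos <- length(unique(func$position))
  ord <- order(func$position, match(func$site_id, sites$site_id))
  func <- func[ord, ]
  f_act <- matrix(func$f_act, nrow(sites), npos)
  f_quench <- matrix(func$f_quench, nrow(sites), npos)
  f_act_q <- quenching_matrix(sites, f_act, f_quench, param_tables(params),
                              config)
  func$f_act_quenched <- as.vector(f_act_q)
  func
}

# Long occupancy tibble -> n_sites x n_pos matrix in `sites` row order.
occ_to_matrix <- function(occ, sites) {
  positions <- sort(unique(occ$position))
  ord <- order(occ$position, match(occ$site_id, sites$site_id))
  f <- matrix(occ$f[ord], nrow(sites), length(positions))
  list(f = f, positions = positions)
}
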