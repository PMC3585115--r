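#' Remove a regulatory mechanism in silico
#'
#' The model's mechanisms are separable, removable and non-exclusive: each
#' is switched off by zeroing (or neutralizing) its parameters while
#' leaving everything else untouched, so predictions with and without a
#' mechanism attribute expression changes to it.
#'
#' * `cooperativity` — all \eqn{\omega} set to 1
#' * `coactivation` — all \eqn{\beta_{co}} set to 0
#' * `quenching` — all \eqn{\beta_Q} set to 0
#' * `direct_repression` — all \eqn{\beta_D} set to 0
#'
#' Knockouts commute and are idempotent.
#'
#' @param params Parameter tibble.
#' @param mechanism Character vector of mechanisms from the set above.
#' @return The modified parameter tibble.
#' @export
apply_knockout <- function(params, mechanism) {
  known <- c("cooperativity", "coactivation", "quenching",
             "direct_repression")
  bad <- setdiff(mechanism, known)
  if (length(bad)) {
    stop("invalid knockout: unknown mechanism ",
         paste(bad, collapse = ", "), "; known: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  for (m in mechanism) {
    target <- switch(m, cooperativity = "omega", coactivation = "beta_co",
                     quenching = "beta_q", direct_repression = "beta_d")
    neutral <- if (m == "cooperativity") 1 else 0
    params$value[params$param == target] <- neutral
  }
  params
}

#' Drop named sites from a site table
#'
#' Site-level knockout: excludes sites by `site_id` (or by row index) so a
#' prediction can be re-run without them.
#'
#' @param sites Site tibble.
#' @param site_ids Ids of sites to remove.
#' @return The filtered site tibble.
#' @export
mask_sites <- function(sites, site_ids) {
  sites <- ensure_site_id(sites)
  sites[!sites$site_id %in% site_ids, ]
}

#' Dissect a prediction into per-site activation contributions
#'
#' Produces the activation map used to attribute expression to individual
#' binding sites: for each anterior-posterior position and each
#' activator-acting site, the contribution
#' \eqn{\Delta E_i = \alpha_i f^{AQ}_i} to the summed activation, together
#' with the per-position totals before (`E_raw`) and after (`E_eff`)
#' direct repression and the predicted rate. Site coordinates are also
#' reported as bp 5' of the TSS for plotting against the sequence axis.
#'
#' @inheritParams predict_profile
#' @return An object of class `dissection_map`: a list with `grid` (long
#'   tibble `position`, `site_id`, `tf`, `bp_5prime_of_tss`, `delta_E`),
#'   `totals` (`position`, `E_raw`, `E_eff`, `rate`), `sites`, and
#'   `construct`.
#' @export
dissect <- function(construct, pwms, tf_profiles, params,
                    config = default_model_config(), knockout = NULL) {
  pred <- predict_profile(construct, pwms, tf_profiles, params, config,
                          knockout = knockout, details = TRUE)
  sites <- attr(pred, "sites")
  construct <- as.list(construct)
  if (is.null(sites) || nrow(sites) == 0) {
    warning("construct has no binding sites: empty dissection map",
            call. = FALSE)
    return(structure(list(grid = tibble::tibble(), totals = tibble::tibble(),
                          sites = sites, construct = construct$construct),
                     class = "dissection_map"))
  }
  func <- attr(pred, "functional")
  activation <- attr(pred, "activation")
  alpha <- site_alphas(sites, param_tables(params), config)
  grid <- func |>
    dplyr::mutate(
      tf = sites$tf[match(.data$site_id, sites$site_id)],
      bp_5prime_of_tss =
        construct$tss - sites$center[match(.data$site_id, sites$site_id)],
      delta_E = alpha[match(.data$site_id, sites$site_id)] *
        .data$f_act_quenched
    ) |>
    dplyr::select("position", "site_id", "tf", "bp_5prime_of_tss",
                  "delta_E")
  totals <- activation |>
    dplyr::mutate(rate = pred$rate[match(.data$position, pred$position)])
  structure(list(grid = grid, totals = totals, sites = sites,
                 construct = construct$construct),
            class = "dissection_map")
}

#' @export
print.dissection_map <- function(x, ...) {
  cat("<dissection_map> ", x$construct, ": ",
      nrow(x$sites %||% tibble::tibble()), " sites x ",
      length(unique(x$grid$position)), " positions\n", sep = "")
  invisible(x)
}

#' Tidy a dissection map
#'
#' @param x A `dissection_map`.
#' @param ... Unused.
#' @return The long per-site activation grid joined with per-position
#'   totals.
#' @exportS3Method generics::tidy
tidy.dissection_map <- function(x, ...) {
  dplyr::left_join(x$grid, x$totals, by = "position")
}

#' Export a dissection map as a matrix plus site annotations
#'
#' @param x A `dissection_map`.
#' @return A list with `matrix` (positions x sites, \eqn{\Delta E}),
#'   `annotation` (BED-flavored site table), and `totals`.
#' @export
dissection_matrix <- function(x) {
  stopifnot(inherits(x, "dissection_map"))
  wide <- tidyr::pivot_wider(x$grid[, c("position", "site_id", "delta_E")],
                             names_from = "site_id",
                             values_from = "delta_E")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$position
  ann <- x$sites[, c("tf", "start", "end", "strand", "score")]
  ann$construct <- x$construct
  list(matrix = m, annotation = ann, totals = x$totals)
}
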