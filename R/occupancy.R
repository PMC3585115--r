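#' Assign pairwise cooperative interactions among sites of one factor
#'
#' Greedy pairing rule for homotypic cooperativity: the strongest (highest
#' relative affinity) unpaired site is paired with the strongest remaining
#' unpaired site whose center lies within `range_bp`; both are then marked
#' paired and the rule is repeated until no assignable pair remains. Sites
#' left over carry no cooperativity weight. Distances are measured center
#' to center of the match intervals. Affinity ties are broken toward the
#' smaller start coordinate, for determinism.
#'
#' @param sites A site tibble (as from [scan_sequence()]) restricted to
#'   the cooperative factor; must carry a `site_id` column (added if
#'   absent, as the row number).
#' @param range_bp Maximum center-to-center pairing distance. Default 60.
#' @return A tibble with columns `site_a`, `site_b` (site_ids, a = the
#'   stronger member) — one row per cooperative pair.
#' @export
assign_cooperativity <- function(sites, range_bp = 60) {
  sites <- ensure_site_id(sites)
  n <- nrow(sites)
  empty <- tibble::tibble(site_a = integer(), site_b = integer())
  if (n < 2) return(empty)
  if (length(unique(sites$tf)) > 1) {
    stop("cooperative pairing is homotypic: sites must all belong to one TF",
         call. = FALSE)
  }
  ord <- order(-sites$rel_affinity, sites$start)
  available <- rep(TRUE, n)
  pairs <- list()
  for (i in ord) {
    if (!available[i]) next
    cand <- which(available & seq_len(n) != i &
                    abs(sites$center - sites$center[i]) <= range_bp)
    if (length(cand) == 0) {
      available[i] <- FALSE  # permanently unpaired
      next
    }
    j <- cand[order(-sites$rel_affinity[cand], sites$start[cand])][1]
    pairs[[length(pairs) + 1L]] <-
      c(sites$site_id[i], sites$site_id[j])
    available[c(i, j)] <- FALSE
  }
  if (length(pairs) == 0) return(empty)
  m <- do.call(rbind, pairs)
  tibble::tibble(site_a = m[, 1], site_b = m[, 2])
}

ensure_site_id <- function(sites) {
  if (!"site_id" %in% names(sites)) sites$site_id <- seq_len(nrow(sites))
  sites
}

# TRUE where footprint intervals overlap (0-based half-open).
footprint_conflicts <- function(sites) {
  n <- nrow(sites)
  outer(sites$fp_start, sites$fp_end, `<`) &
    t(outer(sites$fp_start, sites$fp_end, `<`)) &
    !diag(TRUE, n)
}

#' Partition sites into independent binding groups
#'
#' Builds a graph with an edge for every steric footprint overlap and
#' every cooperative pair, and labels each connected component as one
#' group. The partition function of the full site set factorizes exactly
#' over these groups, so fractional occupancies can be computed per group
#' without approximation.
#'
#' @param sites Site tibble covering all factors on a construct, with
#'   `fp_start`/`fp_end` footprint columns.
#' @param pairs Cooperative pairs from [assign_cooperativity()].
#' @param max_group_size Enumeration cap; a component larger than this
#'   raises an error rather than approximating. Default 20.
#' @return `sites` with `site_id` and an integer `group` column added
#'   (groups numbered in order of leftmost site).
#' @export
build_site_groups <- function(sites, pairs = NULL, max_group_size = 20) {
  sites <- ensure_site_id(sites)
  n <- nrow(sites)
  if (n == 0) {
    sites$group <- integer(0)
    return(sites)
  }
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) parent[find(a)] <<- find(b)

  conf <- footprint_conflicts(sites)
  for (i in seq_len(n)) {
    js <- which(conf[i, ] & seq_len(n) > i)
    for (j in js) union_(i, j)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    ia <- match(pairs$site_a, sites$site_id)
    ib <- match(pairs$site_b, sites$site_id)
    for (k in seq_along(ia)) union_(ia[k], ib[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- match(roots, unique(roots[order(sites$start)]))
  tab <- table(grp)
  if (any(tab > max_group_size)) {
    g <- names(tab)[which.max(tab)]
    span <- range(sites$start[grp == as.integer(g)],
                  sites$end[grp == as.integer(g)])
    stop("group too large for exact enumeration (", max(tab), " sites, ",
         "interval [", span[1], ", ", span[2], ")); raise max_group_size ",
         "or thin the site set", call. = FALSE)
  }
  sites$group <- grp
  dplyr::arrange(sites, .data$group, .data$start)
}

# Enumerate all conflict-free subsets of n sites. Returns a list with
# `cfg` (n_cfg x n 0/1 matrix, first row the empty configuration) and
# `pair_in` (n_cfg x n_pairs 0/1: both pair members present).
enumerate_configs <- function(conflict, pair_idx = NULL) {
  n <- nrow(conflict)
  configs <- list(integer(0))
  for (i in seq_len(n)) {
    ext <- configs[vapply(configs, function(c) !any(conflict[i, c]),
                          logical(1))]
    configs <- c(configs, lapply(ext, function(c) c(c, i)))
  }
  cfg <- matrix(0, length(configs), n)
  for (k in seq_along(configs)) cfg[k, configs[[k]]] <- 1
  np <- if (is.null(pair_idx)) 0L else nrow(pair_idx)
  pair_in <- matrix(0, length(configs), np)
  if (np) {
    for (p in seq_len(np)) {
      pair_in[, p] <- cfg[, pair_idx[p, 1]] * cfg[, pair_idx[p, 2]]
    }
  }
  list(cfg = cfg, pair_in = pair_in)
}

#' Statistical weights of the binding configurations of a site group
#'
#' A configuration is a subset of the group's sites in which no two
#' members have overlapping footprints (steric exclusion). Its weight is
#' the product of the site weights \eqn{q_i = K_i D_a v_a} of the bound
#' sites, multiplied by the cooperativity factor \eqn{\omega} for every
#' cooperative pair bound simultaneously. The empty configuration has
#' weight 1.
#'
#' @param sites Site tibble for one group (footprint columns required).
#' @param q Named or positional numeric vector of site weights
#'   \eqn{q_i \ge 0}, one per site.
#' @param omega Cooperativity factor(s): scalar recycled over pairs, or a
#'   vector of length `nrow(pairs)`.
#' @param pairs Cooperative pairs internal to the group (site_id pairs).
#' @return A tibble with `config_id`, `sites` (list-column of site_ids
#'   bound), `n_bound`, and `weight`, first row the empty configuration.
#' @export
configuration_weights <- function(sites, q, omega = 1, pairs = NULL) {
  sites <- ensure_site_id(sites)
  if (any(q < 0)) stop("invalid concentration: negative site weight q",
                       call. = FALSE)
  stopifnot(length(q) == nrow(sites))
  pair_idx <- pairs_to_index(pairs, sites)
  en <- enumerate_configs(footprint_conflicts(sites), pair_idx)
  om <- rep_len(omega, ncol(en$pair_in))
  w <- apply(en$cfg, 1, function(r) prod(q[r == 1])) *
    apply(en$pair_in, 1, function(r) prod(om[r == 1]))
  tibble::tibble(
    config_id = seq_len(nrow(en$cfg)),
    sites = lapply(seq_len(nrow(en$cfg)),
                   function(k) sites$site_id[en$cfg[k, ] == 1]),
    n_bound = rowSums(en$cfg),
    weight = as.numeric(w)
  )
}

pairs_to_index <- function(pairs, sites) {
  if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
  keep <- pairs$site_a %in% sites$site_id & pairs$site_b %in% sites$site_id
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(NULL)
  cbind(match(pairs$site_a, sites$site_id), match(pairs$site_b, sites$site_id))
}

#' Fractional occupancy of each binding site
#'
#' Exact equilibrium occupancy by summation over binding configurations:
#' \deqn{f_i = \sum_{c \ni i} W(c) \; / \; \sum_c W(c)}
#' Sites are first partitioned into independent groups (footprint overlap
#' or cooperative pairing); each group's partition function is evaluated
#' separately, which is exact because groups share no interactions.
#'
#' @param sites Site tibble (any number of groups).
#' @param q Site weight vector, one entry per row of `sites`
#'   (\eqn{q_i = K_i D_a v_a}).
#' @param omega Cooperativity factor applied to every pair in `pairs`.
#' @param pairs Cooperative pairs tibble.
#' @param max_group_size Enumeration cap passed to [build_site_groups()].
#' @return A tibble `site_id`, `tf`, `f` with occupancies in \[0, 1\].
#' @export
fractional_occupancy <- function(sites, q, omega = 1, pairs = NULL,
                                 max_group_size = 20) {
  sites <- ensure_site_id(sites)
  f <- occupancy_matrix(sites, matrix(q, ncol = 1), omega = omega,
                        pairs = pairs, max_group_size = max_group_size)
  tibble::tibble(site_id = sites$site_id, tf = sites$tf, f = f[, 1])
}

# Vectorized occupancy over positions: qmat is n_sites x n_pos; returns an
# n_sites x n_pos matrix of fractional occupancies. The configuration
# structure depends only on the site geometry, so it is enumerated once
# per group and the weight sums are evaluated for all positions at once.
occupancy_matrix <- function(sites, qmat, omega = 1, pairs = NULL,
                             max_group_size = 20, compiled = NULL) {
  n <- nrow(sites)
  f <- matrix(0, n, ncol(qmat))
  if (n == 0) return(f)
  if (any(qmat < 0)) stop("invalid concentration: negative site weight q",
                          call. = FALSE)
  comp <- compiled %||% compile_occupancy(sites, pairs, max_group_size)
  logq <- log(pmax(qmat, 1e-300))
  for (g in comp) {
    lw <- g$cfg %*% logq[g$rows, , drop = FALSE]
    if (ncol(g$pair_in)) {
      lw <- lw + (g$pair_in %*% rep_len(log(omega), ncol(g$pair_in)))[, 1]
    }
    w <- exp(lw)
    z <- colSums(w)
    f[g$rows, ] <- crossprod(g$cfg, w) / rep(z, each = length(g$rows))
  }
  f
}

# Precompute group membership and configuration matrices for a site set.
compile_occupancy <- function(sites, pairs = NULL, max_group_size = 20) {
  sites <- ensure_site_id(sites)
  grouped <- build_site_groups(sites, pairs, max_group_size)
  # build_site_groups may reorder; map back to the caller's row order
  rows_of <- match(grouped$site_id, sites$site_id)
  lapply(unique(grouped$group), function(g) {
    idx <- which(grouped$group == g)
    sub <- grouped[idx, ]
    en <- enumerate_configs(footprint_conflicts(sub),
                            pairs_to_index(pairs, sub))
    list(rows = rows_of[idx], cfg = en$cfg, pair_in = en$pair_in)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Occupancy landscape of a construct across anterior-posterior positions
#'
#' Composes site-weight assembly and grouped configuration summation for
#' every position of a concentration table. The site weight is
#' \eqn{q_i = K_i \, D_a \, v_a(x)}: relative affinity times the fitted
#' concentration scale times the observed relative fluorescence of the
#' factor at position \eqn{x}.
#'
#' @param sites Site tibble for one construct.
#' @param concentrations Tibble with a `position` column and one column of
#'   relative fluorescence per TF.
#' @param params Parameter tibble (uses `D` per TF and `omega`).
#' @param pairs Cooperative pairs (computed from the cooperative TF's
#'   sites if NULL and a cooperative factor is configured).
#' @param config Model configuration.
#' @return A long tibble `position`, `site_id`, `tf`, `f`.
#' @export
occupancy_landscape <- function(sites, concentrations, params,
                                pairs = NULL, config = default_model_config()) {
  sites <- ensure_site_id(sites)
  missing_tf <- setdiff(unique(sites$tf), names(concentrations))
  if (length(missing_tf)) {
    stop("missing concentration profile for TF: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  }
  if (is.null(pairs)) {
    coop_tf <- config$tfs$tf[config$tfs$cooperative]
    pairs <- assign_cooperativity(sites[sites$tf %in% coop_tf, ],
                                  config$coop_range_bp)
  }
  D <- param_by_tf(params, "D")
  vmat <- t(as.matrix(concentrations[, sites$tf, drop = FALSE]))
  qmat <- sites$rel_affinity * D[sites$tf] * vmat
  omega <- if (any(params$param == "omega")) {
    params$value[params$param == "omega"][1]
  } else 1
  f <- occupancy_matrix(sites, qmat, omega = omega, pairs = pairs,
                        max_group_size = config$enumeration_cap)
  tibble::tibble(
    position = rep(concentrations$position, each = nrow(sites)),
    site_id = rep(sites$site_id, times = nrow(concentrations)),
    tf = rep(sites$tf, times = nrow(concentrations)),
    f = as.vector(f)
  )
}
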