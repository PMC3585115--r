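# ---- fast compiled evaluation -------------------------------------------
#
# The objective is evaluated ~1e5 times per annealing run, so the per-
# construct pipeline is compiled once into plain matrices: site scans,
# cooperative pairs, configuration matrices, concentration rows per site,
# and TSS range values. Only the PWM score thresholds change the site set;
# the compiled structure is cached keyed on the threshold vector and
# rebuilt when a threshold parameter moves.

compile_construct <- function(construct, pwms, params, config) {
  sites <- scan_construct(construct$seq, pwms, params, config)
  if (nrow(sites) == 0) {
    return(list(sites = sites, empty = TRUE, construct = construct$construct))
  }
  coop_tf <- config$tfs$tf[config$tfs$cooperative]
  pairs <- assign_cooperativity(sites[sites$tf %in% coop_tf, ],
                                config$coop_range_bp)
  sites_plain <- as.data.frame(sites)  # plain-vector access in the hot path
  n <- nrow(sites_plain)
  role <- site_roles(sites_plain, config)
  is_target <- config$tfs$coact_target[match(sites_plain$tf, config$tfs$tf)]
  # coactivator geometry per target site: indices and distances per
  # coactivating factor (range values depend on the free range parameter
  # and are computed at evaluation time from these distances)
  targets <- lapply(which(is_target), function(i) {
    coactivators <- config$coactivation$coactivator[
      config$coactivation$target == sites_plain$tf[i]]
    by_co <- lapply(coactivators, function(co) {
      js <- which(sites_plain$tf == co & seq_len(n) != i)
      list(co = co, js = js,
           d = abs(sites_plain$center[js] - sites_plain$center[i]))
    })
    list(i = i, by_co = by_co[vapply(by_co, function(x) length(x$js) > 0,
                                     logical(1))])
  })
  # quenching geometry: (actor, quencher, range-value) triples with
  # positive range value; actor rows are activator sites plus targets
  rv_q <- quench_range_matrix(sites_plain$center, config)
  actor_rows <- which(role == "activator" | is_target)
  rep_rows <- which(role == "repressor")
  triples <- do.call(rbind, lapply(actor_rows, function(i) {
    j <- rep_rows[rv_q[i, rep_rows] > 0]
    if (length(j)) cbind(i = i, j = j, rv = rv_q[i, j]) else NULL
  }))
  alpha_kind <- ifelse(role == "activator", 1L, ifelse(is_target, 2L, 0L))
  list(
    construct = construct$construct,
    empty = FALSE,
    sites = sites_plain,
    tf = sites_plain$tf,
    score = sites_plain$score,
    n = n,
    role_act = role == "activator",
    rep_rows = rep_rows,
    is_target = is_target,
    targets = targets,
    triples = triples,
    alpha_kind = alpha_kind,
    pairs = pairs,
    occ = compile_occupancy(sites, pairs, config$enumeration_cap),
    max_score = vapply(sites_plain$tf, function(tf) pwms[[tf]]$max_score,
                       numeric(1)),
    rv_q = rv_q,
    rv_tss = range_value(abs(sites_plain$center - construct$tss),
                         config$quench_r_full, config$quench_r_zero)
  )
}

# Evaluate one compiled construct at the current parameters; vmat is the
# n_sites x n_pos matrix of relative fluorescence of each site's factor;
# pt a param_tables() lookup (built once per objective evaluation). The
# interaction layers are inlined over the precompiled geometry.
evaluate_compiled <- function(comp, vmat, params, config, pt = NULL) {
  if (comp$empty) return(rep(0, ncol(vmat)))
  pt <- pt %||% param_tables(params)
  n <- comp$n
  npos <- ncol(vmat)
  lam <- unname(pt$lambda[comp$tf])
  D <- unname(pt$D[comp$tf])
  rel_aff <- exp(lam * (comp$score - comp$max_score))
  qmat <- rel_aff * D * vmat
  f_phys <- occupancy_matrix(comp$sites, qmat, omega = pt$omega,
                             pairs = comp$pairs, compiled = comp$occ)
  # coactivation: split physical occupancy of target sites
  f_act <- matrix(0, n, npos)
  f_quench <- matrix(0, n, npos)
  f_act[comp$role_act, ] <- f_phys[comp$role_act, , drop = FALSE]
  f_quench[comp$rep_rows, ] <- f_phys[comp$rep_rows, , drop = FALSE]
  off <- config$coact_offset_bp
  for (tg in comp$targets) {
    surv <- rep(1, npos)
    for (bc in tg$by_co) {
      beta <- lk0(pt$beta_co, bc$co)
      if (beta == 0) next
      r <- lk0(pt$coact_range, bc$co)
      rv <- range_value(bc$d, r, r + off)
      for (k in which(rv > 0)) {
        surv <- surv * (1 - beta * f_phys[bc$js[k], ] * rv[k])
      }
    }
    f_act[tg$i, ] <- f_phys[tg$i, ] * (1 - surv)
    f_quench[tg$i, ] <- f_phys[tg$i, ] - f_act[tg$i, ]
  }
  # short-range quenching over precompiled in-range pairs
  beta_q <- lk0(pt$beta_q, comp$tf)
  f_act_q <- f_act
  if (!is.null(comp$triples)) {
    tr <- comp$triples
    for (row in seq_len(nrow(tr))) {
      j <- tr[row, 2L]
      if (beta_q[j] == 0) next
      i <- tr[row, 1L]
      f_act_q[i, ] <- f_act_q[i, ] *
        (1 - beta_q[j] * f_quench[j, ] * tr[row, 3L])
    }
  }
  # summed adapter recruitment and direct repression at the TSS
  alpha <- numeric(n)
  k1 <- comp$alpha_kind == 1L
  k2 <- comp$alpha_kind == 2L
  alpha[k1] <- lk0(pt$alpha, comp$tf[k1])
  alpha[k2] <- lk0(pt$alpha_coact, comp$tf[k2])
  E_raw <- colSums(alpha * f_act_q)
  beta_d <- lk0(pt$beta_d, comp$tf)
  surv <- rep(1, npos)
  for (j in which(beta_d > 0 & comp$rv_tss > 0)) {
    surv <- surv * (1 - beta_d[j] * f_quench[j, ] * comp$rv_tss[j])
  }
  scale <- lk0(pt$pos_effect, comp$construct)
  if (scale == 0) scale <- 1
  scale * transcription_rate(E_raw * surv, pt$theta, pt$R_max)
}

compile_training <- function(data, pwms, params, config) {
  cons <- split(data$constructs, seq_len(nrow(data$constructs)))
  comps <- lapply(cons, function(con)
    compile_construct(as.list(con), pwms, params, config))
  names(comps) <- data$constructs$construct
  vmats <- lapply(comps, function(comp) {
    if (comp$empty) {
      matrix(0, 0, nrow(data$profiles))
    } else {
      t(as.matrix(data$profiles[, comp$sites$tf, drop = FALSE]))
    }
  })
  obs <- lapply(names(comps), function(id) {
    rows <- data$observations[data$observations$construct == id, ]
    rows$observed[match(data$profiles$position, rows$position)]
  })
  list(comps = comps, vmats = vmats, obs = obs,
       thresholds = params$value[params$param == "threshold"])
}

# ---- objective ----------------------------------------------------------

#' Sum-of-squares objective of a parameter set on a training set
#'
#' Predicts every construct at every position and accumulates the summed
#' squared difference to the observed expression, together with the root
#' mean square per observation. The observation count is the number of
#' positions times the number of constructs (406 under the default
#' 58-position, 7-construct design).
#'
#' @param params Parameter tibble.
#' @param data A `training_set` (see [simulate_dataset()]).
#' @param pwms Named list of PWMs.
#' @param config Model configuration.
#' @param compiled Optional precompiled training structure (internal).
#' @return A list with `ssq`, `rms`, and `n` (observation count).
#' @export
model_objective <- function(params, data, pwms,
                            config = default_model_config(),
                            compiled = NULL) {
  check_params(params)
  compiled <- compiled %||% compile_training(data, pwms, params, config)
  pt <- param_tables(params)
  ssq <- 0
  n <- 0
  for (k in seq_along(compiled$comps)) {
    pred <- evaluate_compiled(compiled$comps[[k]], compiled$vmats[[k]],
                              params, config, pt = pt)
    obs <- compiled$obs[[k]]
    if (length(obs) != length(pred) || anyNA(obs)) {
      stop("alignment error: observations do not cover the model grid for ",
           compiled$comps[[k]]$construct, call. = FALSE)
    }
    ssq <- ssq + sum((pred - obs)^2)
    n <- n + length(obs)
  }
  list(ssq = ssq, rms = sqrt(ssq / n), n = n)
}

# ---- parameter vector <-> transformed search space ----------------------

free_index <- function(params) which(params$free)

to_search_space <- function(values, scale) {
  ifelse(scale == "log", log(values), values)
}
from_search_space <- function(x, scale) {
  ifelse(scale == "log", exp(x), x)
}

inject_free <- function(params, x, idx, scale) {
  params$value[idx] <- from_search_space(x, scale)
  params
}

reflect_into <- function(x, lo, hi) {
  # reflect a proposal back into [lo, hi]
  for (i in seq_along(x)) {
    while (x[i] < lo[i] || x[i] > hi[i]) {
      if (x[i] < lo[i]) x[i] <- 2 * lo[i] - x[i]
      if (x[i] > hi[i]) x[i] <- 2 * hi[i] - x[i]
    }
  }
  x
}

# ---- fit ----------------------------------------------------------------

#' Fit model parameters to a training set
#'
#' Minimizes the sum-of-squares objective over the free entries of the
#' parameter table within their declared bounds. Scale-type parameters
#' (`D`, `R_max`) are searched in log space; efficiencies and ranges in
#' linear space. Three backends are available:
#'
#' * `"lam_sa"` — simulated annealing with a Lam-style adaptive
#'   temperature schedule: the inverse temperature is adjusted after every
#'   move to track a target acceptance ratio that decays from 0.44,
#'   using running estimates of the objective variance.
#' * `"generic_sa"` — Metropolis annealing with a geometric temperature
#'   schedule and single-coordinate Gaussian moves whose widths shrink
#'   with temperature.
#' * `"multistart_local"` — repeated bounded quasi-Newton (L-BFGS-B)
#'   refinement from random starts until the evaluation budget is spent.
#'
#' The run is fully determined by `(seed, optimizer, budget)`; repeated
#' calls with the same arguments yield identical traces.
#'
#' @param data A `training_set`.
#' @param pwms Named list of PWMs.
#' @param params Starting parameter tibble (bounds + free flags).
#' @param config Model configuration.
#' @param optimizer One of `"lam_sa"`, `"generic_sa"`,
#'   `"multistart_local"`.
#' @param seed Integer seed.
#' @param budget Maximum number of objective evaluations (> 0).
#' @param repeats Number of independent runs with derived seeds; the best
#'   is returned and per-run summaries are kept.
#' @param trace_every Record the trace every this many evaluations.
#' @return An object of class `thermo_fit` with the best parameters, final
#'   `ssq`/`rms`, per-run table, and an objective trace. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_model <- function(data, pwms, params,
                      config = default_model_config(),
                      optimizer = c("generic_sa", "lam_sa",
                                    "multistart_local"),
                      seed = 1, budget = 2e5, repeats = 1,
                      trace_every = 50) {
  optimizer <- match.arg(optimizer)
  if (budget <= 0) stop("invalid budget: must be > 0", call. = FALSE)
  check_params(params)
  idx <- free_index(params)
  if (length(idx) == 0) stop("no free parameters to fit", call. = FALSE)
  if (any(!is.finite(params$lower[idx])) || any(!is.finite(params$upper[idx]))) {
    stop("all free parameters need finite bounds", call. = FALSE)
  }

  runs <- lapply(seq_len(repeats), function(r) {
    run_seed <- (seed + 7919L * (r - 1L)) %% .Machine$integer.max
    fit_single(data, pwms, params, config, optimizer, run_seed,
               budget, trace_every)
  })
  rms <- vapply(runs, function(r) r$rms, numeric(1))
  best <- runs[[which.min(rms)]]
  structure(
    list(params = best$params, ssq = best$ssq, rms = best$rms,
         n_obs = best$n, n_free = length(idx), optimizer = optimizer,
         seed = seed, budget = budget, evals = best$evals,
         trace = best$trace,
         runs = tibble::tibble(run = seq_len(repeats),
                               seed = vapply(runs, function(r) r$seed,
                                             numeric(1)),
                               rms = rms,
                               ssq = vapply(runs, function(r) r$ssq,
                                            numeric(1)))),
    class = "thermo_fit")
}

fit_single <- function(data, pwms, params, config, optimizer, seed,
                       budget, trace_every) {
  idx <- free_index(params)
  scale <- params$scale[idx]
  lo <- to_search_space(params$lower[idx], scale)
  hi <- to_search_space(params$upper[idx], scale)

  env <- new.env(parent = emptyenv())
  env$evals <- 0L
  env$trace <- list()
  env$best_x <- NULL
  env$best_val <- Inf
  env$compiled <- NULL
  env$thresholds <- NULL

  obj <- function(x) {
    if (env$evals >= budget) return(NA_real_)
    p <- inject_free(params, x, idx, scale)
    thr <- p$value[p$param == "threshold"]
    if (is.null(env$compiled) || !identical(thr, env$thresholds)) {
      env$compiled <- compile_training(data, pwms, p, config)
      env$thresholds <- thr
    }
    val <- model_objective(p, data, pwms, config, env$compiled)$ssq
    if (!is.finite(val)) {
      stop("optimizer divergence: non-finite objective", call. = FALSE)
    }
    env$evals <- env$evals + 1L
    if (val < env$best_val) {
      env$best_val <- val
      env$best_x <- x
    }
    if (env$evals %% trace_every == 0L || env$evals == 1L) {
      env$trace[[length(env$trace) + 1L]] <-
        c(env$evals, val, env$best_val)
    }
    val
  }

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  x0 <- to_search_space(params$value[idx], scale)
  x0 <- pmin(pmax(x0, lo), hi)

  switch(optimizer,
         generic_sa = sa_generic(obj, x0, lo, hi, budget),
         lam_sa = sa_lam(obj, x0, lo, hi, budget),
         multistart_local = multistart_local(obj, x0, lo, hi, budget))

  best_params <- inject_free(params, env$best_x, idx, scale)
  res <- model_objective(best_params, data, pwms, config)
  tr <- do.call(rbind, env$trace)
  list(params = best_params, ssq = res$ssq, rms = res$rms, n = res$n,
       evals = env$evals, seed = seed,
       trace = tibble::tibble(eval = tr[, 1], ssq = tr[, 2],
                              best_ssq = tr[, 3]))
}

# Metropolis annealing with a geometric schedule. One coordinate moves
# per step; the proposal width is a fraction of the coordinate's range
# that cools with the temperature.
sa_generic <- function(obj, x0, lo, hi, budget, t0_frac = 1, tf_frac = 1e-4) {
  x <- x0
  fx <- obj(x)
  span <- hi - lo
  t0 <- t0_frac * max(fx, .Machine$double.eps)
  tf <- tf_frac * t0
  k <- 0
  while (TRUE) {
    temp <- t0 * (tf / t0)^(min(1, k / max(1, budget - 2)))
    i <- sample.int(length(x), 1)
    prop <- x
    width <- span[i] * (0.02 + 0.4 * (temp / t0))
    prop[i] <- prop[i] + stats::rnorm(1, 0, width)
    prop <- reflect_into(prop, lo, hi)
    fp <- obj(prop)
    if (is.na(fp)) break
    if (fp <= fx || stats::runif(1) < exp((fx - fp) / temp)) {
      x <- prop
      fx <- fp
    }
    k <- k + 1
  }
  invisible(NULL)
}

# Lam-style adaptive annealing: the inverse temperature is increased
# multiplicatively after every step so that the observed acceptance ratio
# tracks a target that decays from 0.44 toward 0, with single-coordinate
# Gaussian moves whose widths adapt toward 50% acceptance per coordinate.
sa_lam <- function(obj, x0, lo, hi, budget, target0 = 0.44) {
  x <- x0
  fx <- obj(x)
  span <- hi - lo
  n <- length(x)
  width <- span * 0.1
  acc_coord <- rep(0.5, n)
  s <- 1 / max(fx, .Machine$double.eps)   # inverse temperature
  acc_run <- target0
  k <- 0
  while (TRUE) {
    i <- sample.int(n, 1)
    prop <- x
    prop[i] <- prop[i] + stats::rnorm(1, 0, width[i])
    prop <- reflect_into(prop, lo, hi)
    fp <- obj(prop)
    if (is.na(fp)) break
    accepted <- fp <= fx || stats::runif(1) < exp(-s * (fp - fx))
    if (accepted) {
      x <- prop
      fx <- fp
    }
    acc_run <- 0.998 * acc_run + 0.002 * accepted
    acc_coord[i] <- 0.95 * acc_coord[i] + 0.05 * accepted
    # adapt move widths toward 50% per-coordinate acceptance
    width[i] <- min(span[i],
                    max(1e-6 * span[i],
                        width[i] * exp(0.1 * (acc_coord[i] - 0.5))))
    # decay the target acceptance ratio over the budget; push s to track it
    target <- target0 * (1 - min(1, k / max(1, budget - 2)))^2
    s <- s * exp(0.01 * (acc_run - max(target, 0.01)))
    k <- k + 1
  }
  invisible(NULL)
}

# Bounded L-BFGS-B refinements from random starts. The evaluation budget
# is a cap; the search also stops once `max_stale` consecutive restarts
# fail to improve the best objective by a relative margin, so an easy
# landscape does not consume the whole allowance. The first start is the
# supplied initial point.
multistart_local <- function(obj, x0, lo, hi, budget, max_stale = 8,
                             rel_tol = 1e-3) {
  first <- TRUE
  best <- Inf
  stale <- 0
  while (stale < max_stale) {
    start <- if (first) x0 else stats::runif(length(x0), lo, hi)
    first <- FALSE
    res <- tryCatch(
      stats::optim(start, function(x) {
        v <- obj(x)
        if (is.na(v)) stop("budget exhausted", call. = FALSE)
        v
      }, method = "L-BFGS-B", lower = lo, upper = hi,
      control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) break
    if (res$value < best * (1 - rel_tol)) {
      best <- res$value
      stale <- 0
    } else {
      stale <- stale + 1
    }
  }
  invisible(NULL)
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("<thermo_fit> ", x$optimizer, ": ", x$n_free, " free parameters, ",
      x$evals, " evaluations\n  rms ", format(x$rms, digits = 5),
      " over ", x$n_obs, " observations\n", sep = "")
  invisible(x)
}

#' Tidy the free parameters of a fit
#'
#' @param x A `thermo_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `param`, `tf`,
#'   `estimate`, `lower`, `upper`, and `true` when the training set
#'   recorded its generating values.
#' @exportS3Method generics::tidy
tidy.thermo_fit <- function(x, ...) {
  out <- x$params[x$params$free, c("param", "tf", "value", "lower", "upper")]
  names(out)[names(out) == "value"] <- "estimate"
  tibble::as_tibble(out)
}

#' One-row summary of a fit
#'
#' @param x A `thermo_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ssq`, `rms`, `n_obs`, `n_free`, `evals`,
#'   `optimizer`, `seed`.
#' @exportS3Method generics::glance
glance.thermo_fit <- function(x, ...) {
  tibble::tibble(ssq = x$ssq, rms = x$rms, n_obs = x$n_obs,
                 n_free = x$n_free, evals = x$evals,
                 optimizer = x$optimizer, seed = x$seed)
}
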