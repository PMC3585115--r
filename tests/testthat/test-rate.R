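test_that("summed activation adds alpha-weighted active occupancies", {
  cfg <- fixture_config()
  p <- default_params(cfg)
  width <- 10
  mk <- function(centers, tfs) {
    start <- as.integer(centers - width / 2)
    tibble::tibble(site_id = seq_along(centers), tf = tfs,
                   start = start, end = start + width, strand = "+",
                   score = 0, rel_affinity = 1, fp_start = start,
                   fp_end = start + width, center = start + width / 2)
  }
  s <- mk(c(100, 300, 500), c("Bcd", "Dst", "Kr"))
  func <- tibble::tibble(
    position = rep(c(40, 60), each = 3),
    site_id = rep(1:3, 2), tf = rep(s$tf, 2),
    f_quench = rep(c(0, 0, 0.5), 2),
    f_act_quenched = rep(c(0.5, 0.25, 0), 2)
  )
  p1 <- set_param(set_param(p, "alpha", 2, "Bcd"), "alpha", 4, "Dst")
  act <- sum_activation(func, s, p1, cfg)
  expect_equal(act$E_raw, rep(2 * 0.5 + 4 * 0.25, 2))

  # no occupied activators -> zero
  func0 <- dplyr::mutate(func, f_act_quenched = 0)
  expect_equal(sum_activation(func0, s, p1, cfg)$E_raw, c(0, 0))

  # negative recruiting strength rejected
  expect_error(sum_activation(func, set_param(p, "alpha", -1), s = s,
                              config = cfg),
               "alpha")
})

test_that("direct repression attenuates activation by TSS-proximal quenchers", {
  cfg <- fixture_config()
  p <- default_params(cfg)
  width <- 10
  start <- as.integer(c(100, 960) - width / 2)
  s <- tibble::tibble(site_id = 1:2, tf = c("Bcd", "Kr"),
                      start = start, end = start + width, strand = "+",
                      score = 0, rel_affinity = 1, fp_start = start,
                      fp_end = start + width, center = start + width / 2)
  func <- tibble::tibble(position = rep(40, 2), site_id = 1:2,
                         tf = s$tf, f_quench = c(0, 1))
  act <- tibble::tibble(position = 40, E_raw = 3)

  # quencher at the TSS with beta_D = 1 silences completely
  p1 <- set_param(p, "beta_d", 1, "Kr")
  out <- apply_direct_repression(act, func, s, tss = 965, params = p1,
                                 config = cfg)
  expect_equal(out$E_eff, 0, tolerance = 1e-12)

  # no quenchers near the TSS: E_eff = E_raw
  out2 <- apply_direct_repression(act, func, s, tss = 2000, params = p1,
                                  config = cfg)
  expect_equal(out2$E_eff, 3)

  # beyond r_zero: no effect regardless of occupancy
  out3 <- apply_direct_repression(act, func, s,
                                  tss = 965 + cfg$quench_r_zero + 1,
                                  params = p1, config = cfg)
  expect_equal(out3$E_eff, 3)
})

test_that("three-state steady state matches an independent linear solve", {
  # all rates 1: (1/2, 1/4, 1/4)
  expect_equal(unname(three_state_steady_state(1, 1, 1, 1)),
               c(0.5, 0.25, 0.25), tolerance = 1e-14)
  # k2 -> 0: initiation occupancy vanishes
  p_small <- three_state_steady_state(1, 1, 1e-9, 1)
  expect_lt(p_small[["P3"]], 1e-8)
  # k1 dominant: state 1 empties
  p_fast <- three_state_steady_state(1e6, 1, 1, 1)
  expect_lt(p_fast[["P1"]], 1e-5)
  expect_equal(unname(p_fast),
               oracle_three_state(1e6, 1, 1, 1), tolerance = 1e-9)

  set.seed(17)
  for (rep in 1:200) {
    k <- exp(runif(4, -4, 4))
    ours <- three_state_steady_state(k[1], k[2], k[3], k[4])
    ref <- oracle_three_state(k[1], k[2], k[3], k[4])
    expect_equal(unname(ours), ref, tolerance = 1e-10)
    expect_equal(sum(ours), 1, tolerance = 1e-12)
  }
  expect_error(three_state_steady_state(1, 0, 1, 1), "invalid rate")
})

test_that("rate law is logistic in energy with the documented asymptotics", {
  expect_equal(transcription_rate(5, 5, 100), 50)   # E = theta -> R_max/2
  expect_lt(transcription_rate(0, 40, 100), 1e-15)  # large barrier -> 0
  expect_lt(transcription_rate(20, 5, 100), 100)    # strictly below R_max
  expect_lte(transcription_rate(1e3, 5, 100), 100)  # stable at saturation
  expect_gt(transcription_rate(50, 5, 100), 99.99)
  e <- seq(-5, 25, by = 0.5)
  r <- transcription_rate(e, 10, 100)
  expect_true(all(diff(r) > 0))
  # exponential regime: log-rate slope ~ 1 per unit energy when K << 1
  slopes <- diff(log(r[e < 0]))
  expect_equal(slopes, rep(0.5, length(slopes)), tolerance = 1e-3)
  expect_error(transcription_rate(1, 1, 0), "R_max")
})

test_that("closed-form rate equals the Markov state-3 occupancy under the substitution", {
  grid <- seq(-8, 12, by = 0.25)
  theta <- 4.5
  p3 <- vapply(grid, function(e) {
    k <- markov_rates_from_energy(e, theta)
    three_state_steady_state(k["k1"], k["k_minus1"], k["k2"],
                             k["k3"])[["P3"]]
  }, numeric(1))
  p3_max <- 0.5  # limit of P3 as the barrier vanishes under k2 = k3
  expect_equal(p3 / p3_max,
               transcription_rate(grid, theta, 1), tolerance = 1e-12)
})

test_that("profile prediction composes the pipeline position by position", {
  cfg <- fixture_config()
  pwms <- fixture_pwms()
  p <- default_params(cfg)
  prof <- fixture_profiles()

  # all concentrations zero -> flat zero-rate profile (up to the rate floor)
  zero_prof <- dplyr::mutate(prof,
                             dplyr::across(-"position", ~ 0 * .x))
  con <- generate_construct(
    tibble::tibble(tf = c("Bcd", "Dst"), offset = c(50, 120)),
    length = 300, seed = 2, id = "Z")
  pz <- predict_profile(con, pwms, zero_prof, p, cfg)
  floor_rate <- transcription_rate(0, param_value(p, "theta"),
                                   param_value(p, "R_max"))
  expect_equal(pz$rate, rep(floor_rate, nrow(prof)), tolerance = 1e-12)

  # single activator under one concentration bump peaks with the bump
  bump_prof <- dplyr::mutate(zero_prof,
                             Kr = exp(-((position - 60) / 6)^2))
  con_kr <- generate_construct(tibble::tibble(tf = "Kr", offset = 80),
                               length = 300, seed = 3, id = "K")
  cfg_act <- cfg
  cfg_act$tfs$role[cfg_act$tfs$tf == "Kr"] <- "activator"
  p_act <- default_params(cfg_act)
  pk <- predict_profile(con_kr, pwms, bump_prof, p_act, cfg_act)
  expect_equal(pk$position[which.max(pk$rate)],
               bump_prof$position[which.max(bump_prof$Kr)])
  expect_true(all(diff(pk$rate[pk$position <= 60]) >= -1e-12))

  # rates bounded by the scaled saturating rate
  cons <- default_constructs(seed = 1)
  pr <- predict_profile(cons$M32, pwms, prof, p, cfg)
  expect_true(all(pr$rate >= 0 & pr$rate < param_value(p, "R_max")))
})

test_that("prediction is monotone in activator and repressor concentrations", {
  cfg <- fixture_config()
  pwms <- fixture_pwms()
  p <- default_params(cfg)
  prof <- fixture_profiles()
  con <- default_constructs(seed = 4)$M32
  base <- predict_profile(con, pwms, prof, p, cfg)
  up_act <- dplyr::mutate(prof, Bcd = Bcd * 1.5)
  up_rep <- dplyr::mutate(prof, Kr = Kr * 1.5)
  pa <- predict_profile(con, pwms, up_act, p, cfg)
  pr <- predict_profile(con, pwms, up_rep, p, cfg)
  expect_true(all(pa$rate >= base$rate - 1e-9))
  expect_true(all(pr$rate <= base$rate + 1e-9))
})

test_that("with every interaction removed the model reduces to independent activators", {
  cfg <- fixture_config()
  pwms <- fixture_pwms()
  prof <- fixture_profiles()
  p <- default_params(cfg)
  p_off <- apply_knockout(p, c("cooperativity", "coactivation",
                               "quenching", "direct_repression"))
  con <- default_constructs(seed = 5)$M3_2
  pred <- predict_profile(con, pwms, prof, p_off, cfg, details = TRUE)
  # E_raw must now be the sum over activator sites of alpha * f_phys
  sites <- attr(pred, "sites")
  occ <- attr(pred, "occupancy")
  act <- attr(pred, "activation")
  role <- cfg$tfs$role[match(sites$tf, cfg$tfs$tf)]
  pt <- thermotrx:::param_tables(p_off)
  manual <- occ |>
    dplyr::mutate(role = role[match(site_id, sites$site_id)],
                  a = ifelse(role == "activator",
                             thermotrx:::lk0(pt$alpha,
                                             tf), 0)) |>
    dplyr::group_by(position) |>
    dplyr::summarise(E = sum(a * f), .groups = "drop")
  expect_equal(act$E_raw, manual$E, tolerance = 1e-12)
  expect_equal(act$E_eff, act$E_raw, tolerance = 1e-12)
})
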