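sites_at <- function(centers, affinities, tf = "Bcd", width = 10) {
  start <- as.integer(centers - width / 2)
  tibble::tibble(
    site_id = seq_along(centers), tf = tf,
    start = start, end = start + as.integer(width),
    strand = "+", score = log(affinities),
    rel_affinity = affinities,
    fp_start = start, fp_end = start + as.integer(width),
    center = start + width / 2
  )
}

test_that("greedy cooperativity pairing follows the strongest-first rule", {
  # strongest pairs with strongest-in-range; out-of-range site left alone
  s <- sites_at(c(100, 130, 400), c(0.9, 0.5, 0.4))
  p <- assign_cooperativity(s, range_bp = 60)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$site_a, p$site_b), c(1L, 2L))

  # a single site never pairs
  expect_equal(nrow(assign_cooperativity(sites_at(100, 0.9))), 0L)

  # four in-range sites pair strongest-with-next-strongest, twice
  s4 <- sites_at(c(100, 115, 130, 145), c(0.9, 0.8, 0.7, 0.6))
  p4 <- assign_cooperativity(s4, range_bp = 60)
  expect_equal(nrow(p4), 2L)
  expect_equal(sort(paste(pmin(p4$site_a, p4$site_b),
                          pmax(p4$site_a, p4$site_b))),
               c("1 2", "3 4"))

  # exact 60 bp separation is within range; 61 bp is not
  s_edge <- sites_at(c(100, 160), c(0.9, 0.8))
  expect_equal(nrow(assign_cooperativity(s_edge, 60)), 1L)
  s_out <- sites_at(c(100, 161), c(0.9, 0.8))
  expect_equal(nrow(assign_cooperativity(s_out, 60)), 0L)

  # heterotypic input is rejected
  s_mixed <- dplyr::bind_rows(sites_at(100, 0.9),
                              sites_at(130, 0.8, tf = "Kr"))
  s_mixed$site_id <- 1:2
  expect_error(assign_cooperativity(s_mixed), "homotypic")
})

test_that("pairing skips a strongest site with no in-range partner", {
  # strongest site isolated; remaining two pair among themselves
  s <- sites_at(c(500, 100, 140), c(0.95, 0.6, 0.5))
  p <- assign_cooperativity(s, 60)
  expect_equal(nrow(p), 1L)
  expect_setequal(c(p$site_a, p$site_b), c(2L, 3L))
})

test_that("groups are connected components of overlap and cooperativity edges", {
  # disjoint footprints, no pairs: singleton groups
  s <- sites_at(c(100, 200), c(0.5, 0.5))
  g <- build_site_groups(s)
  expect_equal(g$group, c(1L, 2L))

  # chained overlaps A-B, B-C merge into one group
  s3 <- sites_at(c(100, 107, 114), c(0.5, 0.5, 0.5))
  g3 <- build_site_groups(s3)
  expect_equal(g3$group, c(1L, 1L, 1L))

  # a cooperative pair merges two footprint-disjoint sites
  s2 <- sites_at(c(100, 150), c(0.9, 0.8))
  pairs <- assign_cooperativity(s2, 60)
  g2 <- build_site_groups(s2, pairs)
  expect_equal(g2$group, c(1L, 1L))
  expect_equal(build_site_groups(s2)$group, c(1L, 2L))

  # enumeration cap raises with the offending interval
  dense <- sites_at(seq(100, 100 + 5 * 24, by = 5), rep(0.5, 25))
  expect_error(build_site_groups(dense, max_group_size = 20), "too large")
})

test_that("configuration weights implement steric exclusion and cooperativity", {
  # two overlapping sites: joint binding excluded
  s <- sites_at(c(100, 105), c(1, 1))
  cw <- configuration_weights(s, q = c(1, 1))
  expect_equal(sort(vapply(cw$sites, length, integer(1))), c(0L, 1L, 1L))
  expect_equal(cw$weight, c(1, 1, 1))

  # two non-overlapping cooperative sites with omega = 2
  s2 <- sites_at(c(100, 150), c(1, 1))
  pairs <- tibble::tibble(site_a = 1L, site_b = 2L)
  cw2 <- configuration_weights(s2, q = c(1, 1), omega = 2, pairs = pairs)
  expect_equal(nrow(cw2), 4L)
  w <- cw2$weight[order(cw2$n_bound, vapply(cw2$sites, function(x)
    sum(x), numeric(1)))]
  expect_equal(w, c(1, 1, 1, 2))

  # omega = 1 factorizes: Z = prod(1 + q_i) for independent sites
  s3 <- sites_at(c(100, 150, 220), c(1, 1, 1))
  q3 <- c(0.5, 2, 3)
  cw3 <- configuration_weights(s3, q = q3, omega = 1)
  expect_equal(sum(cw3$weight), prod(1 + q3))
  expect_error(configuration_weights(s3, q = c(-1, 1, 1)),
               "invalid concentration")
})

test_that("closed-form occupancies: isotherm, competition, cooperative pair", {
  # lone site: Langmuir isotherm q/(1+q)
  s1 <- sites_at(100, 1)
  expect_equal(fractional_occupancy(s1, q = 1)$f, 1 / 2, tolerance = 1e-12)
  expect_equal(fractional_occupancy(s1, q = 3)$f, 3 / 4, tolerance = 1e-12)

  # two overlapping sites: q_i / (1 + q1 + q2)
  s2 <- sites_at(c(100, 105), c(1, 1))
  f2 <- fractional_occupancy(s2, q = c(1, 1))$f
  expect_equal(f2, c(1 / 3, 1 / 3), tolerance = 1e-12)
  f2b <- fractional_occupancy(s2, q = c(2, 0.5))$f
  expect_equal(f2b, c(2, 0.5) / 3.5, tolerance = 1e-12)

  # cooperative pair, q = 1, omega = 2: f = (1 + 2) / (1 + 1 + 1 + 2)
  s3 <- sites_at(c(100, 150), c(1, 1))
  pairs <- tibble::tibble(site_a = 1L, site_b = 2L)
  f3 <- fractional_occupancy(s3, q = c(1, 1), omega = 2, pairs = pairs)$f
  expect_equal(f3, c(3 / 5, 3 / 5), tolerance = 1e-12)
})

test_that("grouped computation equals global subset enumeration", {
  set.seed(42)
  for (rep in 1:120) {
    n <- sample(2:9, 1)
    s <- random_site_set(n)
    pairs <- NULL
    omega <- 1
    if (n >= 4 && rep %% 2 == 0) {
      pairs <- tibble::tibble(site_a = 1L, site_b = 2L)
      omega <- runif(1, 1, 5)
    }
    q <- runif(n, 0, 10)
    f <- fractional_occupancy(s, q, omega = omega, pairs = pairs)$f
    f_oracle <- oracle_occupancy(s$fp_start, s$fp_end, q, pairs, omega)
    expect_equal(f, f_oracle, tolerance = 1e-12)
  }
})

test_that("occupancy is monotone in own weight and in competitors' weights", {
  set.seed(5)
  for (rep in 1:25) {
    s <- random_site_set(5)
    q <- runif(5, 0.1, 5)
    f0 <- fractional_occupancy(s, q)$f
    # raise own q
    q_up <- q; q_up[2] <- q[2] * 1.5
    f_up <- fractional_occupancy(s, q_up)$f
    expect_gte(f_up[2], f0[2] - 1e-12)
    # raising a conflicting site's weight never raises f of its rivals
    conflicts <- which(s$fp_start < s$fp_end[2] & s$fp_start[2] < s$fp_end &
                         seq_len(5) != 2)
    for (j in conflicts) {
      expect_lte(f_up[j], f0[j] + 1e-12)
    }
  }
})

test_that("cooperativity never decreases the occupancy of either partner", {
  set.seed(6)
  for (rep in 1:25) {
    s <- random_site_set(6)
    q <- runif(6, 0.1, 5)
    pairs <- tibble::tibble(site_a = 3L, site_b = 5L)
    f1 <- fractional_occupancy(s, q, omega = 1, pairs = pairs)$f
    fw <- fractional_occupancy(s, q, omega = runif(1, 1, 8), pairs = pairs)$f
    expect_gte(fw[3], f1[3] - 1e-12)
    expect_gte(fw[5], f1[5] - 1e-12)
  }
})

test_that("configuration probabilities normalize exactly", {
  set.seed(8)
  s <- random_site_set(7)
  q <- runif(7, 0, 4)
  cw <- configuration_weights(s, q)
  expect_equal(sum(cw$weight / sum(cw$weight)), 1, tolerance = 1e-15)
  # mutually conflicting sites: summed occupancy bounded by 1
  f <- fractional_occupancy(s, q)$f
  overlap_group <- which(s$fp_start < min(s$fp_end) )
  expect_lte(sum(f[overlap_group]), 1 + 1e-12)
})

test_that("occupancy landscape composes scan, pairing and grouping over positions", {
  cfg <- fixture_config()
  p <- default_params(cfg)
  s <- dplyr::bind_rows(
    sites_at(c(100, 140), c(1, 0.8), tf = "Bcd"),
    sites_at(300, 1, tf = "Kr")
  )
  s$site_id <- seq_len(nrow(s))
  conc <- tibble::tibble(position = c(35, 50, 92),
                         Bcd = c(1, 0.3, 0), Kr = c(0, 1, 0))
  land <- occupancy_landscape(s, conc, p, config = cfg)
  expect_equal(nrow(land), 9L)
  expect_true(all(land$f >= 0 & land$f <= 1))
  # zero concentration everywhere -> zero occupancy
  expect_true(all(land$f[land$position == 92] < 1e-200))
  # doubling D equals doubling the fluorescence profile
  p2 <- set_param(p, "D", param_value(p, "D", "Bcd") * 2, tf = "Bcd")
  conc2 <- dplyr::mutate(conc, Bcd = Bcd * 2)
  l_d <- occupancy_landscape(s, conc, p2, config = cfg)
  l_v <- occupancy_landscape(s, conc2, p, config = cfg)
  expect_equal(l_d$f, l_v$f, tolerance = 1e-12)
  # missing TF profile errors by name
  expect_error(occupancy_landscape(s, conc[, 1:2], p, config = cfg), "Kr")
})

test_that("landscape is independent of site evaluation order", {
  cfg <- fixture_config()
  p <- default_params(cfg)
  set.seed(13)
  s <- random_site_set(8)
  s$tf <- sample(c("Bcd", "Kr", "Hb"), 8, TRUE)
  conc <- tibble::tibble(position = c(40, 60), Bcd = c(1, .5),
                         Kr = c(.2, 1), Hb = c(.7, .1))
  perm <- sample(8)
  s_perm <- s[perm, ]
  a <- occupancy_landscape(s, conc, p, config = cfg)
  b <- occupancy_landscape(s_perm, conc, p, config = cfg)
  merged <- dplyr::left_join(a, b, by = c("position", "site_id"))
  expect_equal(merged$f.x, merged$f.y, tolerance = 1e-12)
})
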