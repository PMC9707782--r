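test_that("default design yields the study layout", {
  b <- study_bundle()
  expect_equal(nrow(b$sites), 54)
  expect_equal(as.integer(table(b$sites$stratum)[c("urban", "rural",
                                                   "wild")]),
               c(11L, 19L, 24L))
  expect_equal(nrow(b$site_months), 54 * 13)
  expect_equal(sort(unique(b$site_months$month))[1], "2018-07")
  expect_true(all(b$deployments$active_days <=
                    c(31, 31, 30, 31, 30, 31, 31, 28, 31, 30, 31, 30, 31)[
                      match(substr(b$deployments$month, 6, 7),
                            c("07", "08", "09", "10", "11", "12", "01",
                              "02", "03", "04", "05", "06", "07"))] |
                    b$deployments$active_days >= 0))
})

test_that("bundle generation is deterministic under the seed", {
  b1 <- generate_study(truth_config(seed = 55,
                                    strata_sizes = c(urban = 3, rural = 4,
                                                     wild = 5),
                                    n_months = 4))
  b2 <- generate_study(truth_config(seed = 55,
                                    strata_sizes = c(urban = 3, rural = 4,
                                                     wild = 5),
                                    n_months = 4))
  expect_identical(b1$site_months, b2$site_months)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$covariates, b2$covariates)
})

test_that("simulated counts obey degenerate limits", {
  dep <- flat_deployments(c(urban = 5, rural = 5, wild = 5),
                          months = c("2018-07", "2018-08"))
  # pi = 1: everything zero
  t1 <- truth_config(zi_prob = 1, seed = 2)
  withr::with_seed(2, c1 <- simulate_counts(t1, dep))
  expect_true(all(c1$count == 0))
  # Poisson limit: pi = 0, huge theta, sigma = 0 -> variance ~ mean
  t2 <- truth_config(zi_prob = 0, dispersion = 1e7, sigma_site = 0,
                     season_amp = 0, beta0 = -2.5,
                     beta_stratum = c(urban = 0, rural = 0), seed = 3)
  dep_big <- flat_deployments(c(urban = 200, rural = 200, wild = 200),
                              months = sprintf("2018-%02d", 1:12))
  withr::with_seed(3, c2 <- simulate_counts(t2, dep_big))
  expect_gt(nrow(c2), 7000) # enough draws for the moment check
  expect_equal(var(c2$count) / mean(c2$count), 1, tolerance = 0.08)
  # zero effort forces zero counts
  dep0 <- dep
  dep0$active_days[1] <- 0
  withr::with_seed(4, c3 <- simulate_counts(truth_config(), dep0))
  expect_equal(c3$count[1], 0L)
})

test_that("empirical zero fraction matches the analytic mixture probability", {
  # analytic P(y=0) under truth, averaged over the random effect by
  # quadrature, vs the empirical zero fraction: within 3 binomial SEs
  t <- truth_config(seed = 6, season_amp = 0)
  dep <- flat_deployments(effort = 24)
  withr::with_seed(6, cnt <- simulate_counts(t, dep))
  bs <- c(t$beta_stratum, wild = 0)
  eta <- t$beta0 + bs[as.character(dep$stratum)] + log(dep$active_days)
  gh_u <- seq(-5, 5, length.out = 801) * t$sigma_site
  p0 <- vapply(eta, function(e) {
    f <- dnorm(gh_u, 0, t$sigma_site)
    nb0 <- (t$dispersion / (t$dispersion + exp(e + gh_u)))^t$dispersion
    t$zi_prob + (1 - t$zi_prob) *
      sum(f * nb0) / sum(f)
  }, numeric(1))
  expected <- mean(p0)
  observed <- mean(cnt$count == 0)
  se <- sqrt(expected * (1 - expected) / nrow(dep))
  expect_lt(abs(observed - expected), 3 * se + 0.01)
})

test_that("timestamps honour diel windows, stratum probabilities and the gap", {
  t <- truth_config(seed = 12)
  b <- generate_study(t)
  # spacing: every within-site gap is at least the independence gap
  gaps <- b$records |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(min_gap = ifelse(dplyr::n() > 1,
                                      min(diff(as.numeric(timestamp))),
                                      Inf))
  expect_true(all(gaps$min_gap >= t$gap * 60))
  # nocturnal fractions recover the stratum probabilities binomially
  dep <- dplyr::distinct(b$deployments, site_id, stratum)
  rec <- dplyr::left_join(b$records, dep, by = "site_id")
  for (s in c("urban", "rural", "wild")) {
    x <- rec$diel_true[rec$stratum == s] == "night"
    p <- t$nocturnal_probs[[s]]
    expect_lt(abs(mean(x) - p), 3 * sqrt(p * (1 - p) / length(x)) + 0.02)
  }
  # all-day / all-night extremes round-trip through the solar classifier
  t0 <- truth_config(seed = 13, n_months = 2,
                     strata_sizes = c(urban = 2, rural = 2, wild = 2),
                     nocturnal_probs = c(urban = 0, rural = 0, wild = 0))
  b0 <- generate_study(t0)
  ev0 <- classify_diel(independent_events(b0$records), b0$deployments)
  expect_true(all(ev0$diel == "day"))
  t1 <- truth_config(seed = 13, n_months = 2,
                     strata_sizes = c(urban = 2, rural = 2, wild = 2),
                     nocturnal_probs = c(urban = 1, rural = 1, wild = 1))
  b1 <- generate_study(t1)
  ev1 <- classify_diel(independent_events(b1$records), b1$deployments)
  expect_true(all(ev1$diel == "night"))
})

test_that("recovered risk ratio tracks the generating nocturnal contrast", {
  # stratum probabilities (0.52, 0.47, 0.22): RR_urban ~ ln(0.52/0.22)
  b <- study_bundle()
  ev <- classify_diel(independent_events(b$records), b$deployments)
  counts <- nocturnality_counts(ev)
  cu <- counts[counts$stratum == "urban", ]
  cw <- counts[counts$stratum == "wild", ]
  rr <- risk_ratio(cu$O, cu$O_night, cw$O, cw$O_night)
  # binomial sampling oracle: 3 SEs of the realized counts
  se <- sqrt(rr_variance(cu$O, cu$O_night, cw$O, cw$O_night))
  expect_lt(abs(rr - log(0.52 / 0.22)), 3 * se)
})

test_that("generated covariates have the intended correlation structure", {
  b <- study_bundle()
  cov1 <- b$covariates[!duplicated(b$covariates$site_id), ]
  # human density declines from urban to wild
  hd <- tapply(cov1$HD, cov1$stratum, median)
  expect_gt(hd[["urban"]], hd[["rural"]])
  expect_gt(hd[["rural"]], hd[["wild"]])
  # EVI peaks in summer months (S1-style seasonal profile)
  evi <- tapply(b$covariates$EVI, substr(b$covariates$month, 6, 7), mean)
  expect_gt(evi[["07"]], evi[["01"]])
  # conflict probability rises with human density
  expect_gt(cor(b$covariates$conflict_prob, log1p(b$covariates$HD)), 0.5)
  # gridded layer and point counts are usable by the covariate ops
  s1 <- b$sites[1, ]
  expect_gt(weighted_disc_mean(b$hd_grid, c(s1$x, s1$y), 150), 0)
  expect_gte(count_points_in_disc(b$conflict_points, c(s1$x, s1$y), 500), 0)
})
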