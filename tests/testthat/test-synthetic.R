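test_that("generate_drivers: constants, reproducibility, OU moments", {
  tg <- seq(0, 100, by = 1)
  drv <- generate_drivers(tg, list(S = list(process = "constant", value = 1)),
                          seed = 5)
  expect_equal(drv$S(tg), rep(1, length(tg)))

  spec <- list(S = list(process = "sinusoid", mean = 1, amplitude = 0.5,
                        period = 20, noise_sd = 0.1),
               P = list(process = "mean_reverting", rate = 0.5, mean = 0,
                        sd = 0.2))
  d1 <- generate_drivers(tg, spec, seed = 9)
  d2 <- generate_drivers(tg, spec, seed = 9)
  expect_identical(d1$S(tg), d2$S(tg))
  expect_identical(d1$P(tg), d2$P(tg))
  d3 <- generate_drivers(tg, spec, seed = 10)
  expect_false(identical(d1$P(tg), d3$P(tg)))

  # OU stationary moments: mean ~ 0, sd ~ sd/sqrt(2*rate) = 0.2
  tg_long <- seq(0, 9999, by = 1)
  ou <- generate_drivers(tg_long,
                         list(P = list(process = "mean_reverting", rate = 0.5,
                                       mean = 0, sd = 0.2)), seed = 4)
  x <- ou$P(tg_long)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(sd(x) - 0.2 / sqrt(2 * 0.5)) / (0.2 / sqrt(2 * 0.5)), 0.10)

  expect_error(generate_drivers(tg, list(S = list(process = "brownian"))),
               "unknown process")
  expect_error(generate_drivers(tg, list(X = list(process = "constant",
                                                  value = 1))),
               "unknown driver channels")
})

test_that("generate_population matches the per-arm sample sizes", {
  coh <- generate_population(scenario_spec("urban_rural", seed = 2),
                             simulate = FALSE)
  expect_equal(as.integer(table(coh$individuals$arm)[c("urban", "rural")]),
               c(500L, 500L))

  diet <- generate_population(scenario_spec("diet", seed = 2),
                              simulate = FALSE)
  expect_equal(sort(unique(diet$individuals$arm)),
               c("balanced", "high_fat_sugar", "vegetarian"))
  expect_true(all(table(diet$individuals$arm) == 300L))

  soc <- generate_population(scenario_spec("social", seed = 2),
                             simulate = FALSE)
  expect_true(all(table(soc$individuals$arm) == 400L))

  expect_error(scenario_spec("mars_colony"), "unknown scenario")
})

test_that("cohorts are reproducible and unique-id'd", {
  spec <- scenario_spec("income", seed = 77)
  c1 <- generate_population(spec)
  c2 <- generate_population(spec)
  expect_identical(c1$individuals, c2$individuals)
  expect_false(anyDuplicated(c1$individuals$id) > 0)
})

test_that("generated individuals pass all downstream validators", {
  for (seed in 1:5) {
    arms <- list(a1 = list(n = 40, shift = c(beta = 0.5, E_env = -0.5)),
                 a2 = list(n = 40, shift = c()))
    coh <- generate_population(scenario_spec("urban_rural", arms = arms,
                                             seed = seed), simulate = FALSE)
    ind <- coh$individuals
    for (i in seq_len(nrow(ind))) {
      expect_no_error(linear_driver_params(ind$alpha1[i], ind$alpha2[i],
                                           ind$alpha3[i], ind$beta[i]))
      expect_no_error(env_resource_params(ind$alpha_r[i], ind$kappa[i],
                                          ind$beta[i]))
      expect_no_error(logistic_allocation_params(ind$lam_total[i],
                                                 ind$gamma_sens[i]))
      p <- social_cost_params(ind$C0[i], ind$delta_sc[i], ind$eta[i])
      expect_no_error(behavior_cost(ind$S[i], 0, p))  # admissible at Rm = 0
    }
  }
})

test_that("activity contrast yields higher end-of-horizon health", {
  coh <- generate_population(scenario_spec("lifestyle", seed = 123))
  ind <- coh$individuals
  tt <- t.test(ind$H_end[ind$arm == "active"],
               ind$H_end[ind$arm == "sedentary"])
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(ind$H_end[ind$arm == "active"]),
            mean(ind$H_end[ind$arm == "sedentary"]))
})

test_that("all six scenario contrasts point in the configured direction", {
  risk_arm <- c(urban_rural = "urban", income = "low_income",
                lifestyle = "sedentary", diet = "high_fat_sugar",
                social = "low_social", pollution = "high_pollution")
  good_arm <- c(urban_rural = "rural", income = "high_income",
                lifestyle = "active", diet = "balanced",
                social = "high_social", pollution = "low_pollution")
  for (sc in names(risk_arm)) {
    coh <- generate_population(scenario_spec(sc, seed = 321))
    ind <- coh$individuals
    expect_gt(mean(ind$H_end[ind$arm == good_arm[[sc]]]),
              mean(ind$H_end[ind$arm == risk_arm[[sc]]]))
  }
})

test_that("inject_missingness: rates, bursts, value retention", {
  set.seed(6)
  s <- sensor_series(1:1000, rnorm(1000))
  expect_identical(inject_missingness(s, "random", 0, seed = 1), s)

  r <- inject_missingness(s, "random", 0.2, seed = 2)
  expect_lte(abs(sum(r$mask) - 800), 1)
  expect_identical(r$values, s$values)        # originals retained under mask

  b <- inject_missingness(s, "burst", 0.2, max_burst = 5, seed = 3)
  runs <- eldersim:::gap_runs(b$mask)
  expect_true(all(runs$length <= 5))
  expect_gt(nrow(runs), 0)

  expect_error(inject_missingness(s, "random", 1), "rate")
})

test_that("market tables reproduce the survey cells and validate", {
  feats <- load_market_table("features")
  rtm <- feats[feats$feature == "Real-time monitoring", ]
  expect_equal(rtm$importance_pct, 90)
  expect_equal(rtm$availability_pct, 70)
  expect_equal(rtm$technical_difficulty, 4)
  expect_equal(rtm$coverage_5yr_pct, 95)
  pct <- unlist(feats[, c("importance_pct", "availability_pct",
                          "coverage_5yr_pct")])
  expect_true(all(pct >= 0 & pct <= 100))

  conds <- load_market_table("conditions")
  cardio <- conds[conds$condition == "Cardiovascular", ]
  expect_equal(cardio$coverage_pct, 65)
  expect_equal(cardio$population_pct, 35)
  expect_true(all(unlist(conds[, -1]) >= 0 & unlist(conds[, -1]) <= 100))
})

test_that("feature_gap_report sorts importance-availability gaps", {
  rep_tab <- feature_gap_report()
  expect_equal(rep_tab$feature[1], "Cost-effectiveness")
  expect_equal(rep_tab$gap[1], 25)
  expect_equal(rep_tab$gap[rep_tab$feature == "Real-time monitoring"], 20)
  expect_true(all(diff(rep_tab$gap) <= 0))

  flat <- data.frame(feature = c("a", "b"), importance_pct = c(50, 60),
                     availability_pct = c(50, 60))
  expect_true(all(feature_gap_report(flat)$gap == 0))
})

test_that("derive_seed is stable and stream-local", {
  expect_identical(derive_seed(7, "S"), derive_seed(7, "S"))
  expect_false(derive_seed(7, "S") == derive_seed(7, "P"))
  expect_false(derive_seed(7, "S") == derive_seed(8, "S"))
})
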