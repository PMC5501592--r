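test_that("stable scenario holds fertility at baseline with a 0.9/1.1 envelope", {
  s <- stable_scenario(vital_rates())
  expect_equal(nrow(s), 78)                 # calendar years 2009..2086
  expect_equal(range(s$year), c(2009, 2086))
  expect_true(all(s$fertility == 0.85))
  expect_true(all(s$fmin == 0.765))
  expect_true(all(s$fmax == 0.935))

  z <- stable_scenario(vital_rates(adult_fertility = 0))
  expect_true(all(z$fertility == 0) && all(z$fmax == 0))
})

test_that("step scenario is an exactly linear ramp through the 2070 endpoint", {
  s <- step_scenario(0.85, 0.70)
  expect_equal(s$fertility[s$year == 2070], 0.70)
  expect_equal(s$fertility[s$year == 2086], 0.70 + 16 * (-0.15 / 62),
               tolerance = 1e-10)
  expect_equal(s$fertility[s$year == 2086], 0.66129, tolerance = 1e-4)
  # second differences vanish: the yearly change is equivalent in every year
  expect_true(all(abs(diff(diff(s$fertility))) < 1e-12))
  expect_true(all(s$fmin == 0.9 * s$fertility))

  # no change reduces to the stable central series
  flat <- step_scenario(0.85, 0.85)
  expect_true(all(flat$fertility == 0.85))

  # steep declines are floored at zero beyond the endpoint
  crash <- step_scenario(0.85, 0.05)
  expect_true(all(crash$fertility >= 0))
  expect_equal(min(crash$fertility), 0)

  expect_error(step_scenario(0.85, 0.70, endpoint_year = 2100), "outside")
  expect_error(step_scenario(0, 0.7), "\\(0, 1\\]")
})

test_that("yearly-series scenario evaluates envelope corners", {
  b <- logistic_coefficients()
  years <- 2009:2086
  n <- length(years)
  climate <- data.frame(year = years, T = 11, P = 550,
                        T_min = 10, T_max = 12, P_min = 500, P_max = 600)
  s <- yearly_series_scenario(b, climate)
  expect_equal(nrow(s), n)
  # betaT < 0, betaP > 0: min at (T_max, P_min), max at (T_min, P_max)
  expect_equal(s$fmin[1], predict_fertility(b, 12, 500))
  expect_equal(s$fmax[1], predict_fertility(b, 10, 600))
  expect_true(all(s$fmin <= s$fertility & s$fertility <= s$fmax))

  # degenerate ranges collapse the envelope onto the central value
  deg <- data.frame(year = years, T = 11, P = 550,
                    T_min = 11, T_max = 11, P_min = 550, P_max = 550)
  sd_ <- yearly_series_scenario(b, deg)
  expect_equal(sd_$fmin, sd_$fertility)
  expect_equal(sd_$fmax, sd_$fertility)

  # missing years are reported by name
  expect_error(yearly_series_scenario(b, climate[-c(3, 5), ]), "2011.*2013")
})

test_that("scenario envelopes always bracket the central value", {
  b <- logistic_coefficients()
  set.seed(404)
  for (i in 1:20) {
    years <- 2009:2086
    Tc <- runif(length(years), 5, 20)
    Pc <- runif(length(years), 300, 800)
    climate <- data.frame(year = years, T = Tc, P = Pc,
                          T_min = Tc - runif(1, 0, 2), T_max = Tc + runif(1, 0, 2),
                          P_min = pmax(Pc - runif(1, 0, 100), 0),
                          P_max = Pc + runif(1, 0, 100))
    s <- yearly_series_scenario(b, climate)
    expect_true(all(s$fmin <= s$fertility + 1e-12 &
                    s$fertility <= s$fmax + 1e-12))
  }
})

test_that("ensemble endpoint pools models within locations then locations", {
  b <- logistic_coefficients()

  one <- data.frame(id = 1, lon = -105, lat = 40, T_base = 10.85, P_base = 541,
                    T_2070_CC = 13.5, P_2070_CC = 560)
  expect_equal(as.numeric(ensemble_endpoint(b, one)),
               predict_fertility(b, 13.5, 560))

  # two locations with known per-location means average arithmetically
  two <- data.frame(id = 1:2, lon = c(-105, -110), lat = c(40, 35),
                    T_base = 10, P_base = 500,
                    T_2070_CC = c(12, 15), P_2070_CC = c(550, 450))
  m1 <- predict_fertility(b, 12, 550)
  m2 <- predict_fertility(b, 15, 450)
  expect_equal(as.numeric(ensemble_endpoint(b, two)), (m1 + m2) / 2)

  # brute-force double loop oracle on a 50-location, 11-model table
  occ <- gen_occurrence_table(synthetic_spec(seed = 5, n_locations = 50L))
  got <- as.numeric(ensemble_endpoint(b, occ))
  labels <- c("BC", "CC", "GS", "HD", "HE", "IP", "MC", "MI", "MR", "MG", "NO")
  acc <- 0
  for (i in seq_len(nrow(occ))) {
    loc <- 0
    for (lb in labels) {
      loc <- loc + predict_fertility(b, occ[[paste0("T_2070_", lb)]][i],
                                     occ[[paste0("P_2070_", lb)]][i])
    }
    acc <- acc + loc / length(labels)
  }
  expect_equal(got, acc / nrow(occ), tolerance = 1e-12)

  # permutation invariance in locations and models
  occ_perm <- occ[sample(nrow(occ)), ]
  cols <- names(occ)
  model_cols <- grep("_2070_", cols, value = TRUE)
  occ_perm <- occ_perm[c(setdiff(cols, model_cols), sample(model_cols))]
  expect_equal(as.numeric(ensemble_endpoint(b, occ_perm)), got,
               tolerance = 1e-12)

  # missing entries are excluded and counted
  occ_na <- occ
  occ_na$T_2070_CC[1:3] <- NA
  expect_message(res <- ensemble_endpoint(b, occ_na), "3 missing")
  expect_equal(attr(res, "n_excluded"), 3)

  expect_error(ensemble_endpoint(b, occ[0, ]), "empty")
})

test_that("fertility change table computes per-location deltas and grand means", {
  b <- logistic_coefficients()

  # identical baseline and future climate: no change anywhere
  spec0 <- synthetic_spec(seed = 9, n_locations = 30L,
                          model_dT = rep(0, 11), model_dP = rep(0, 11),
                          proj_jitter = 0)
  tab0 <- fertility_change_table(b, gen_occurrence_table(spec0))
  expect_true(all(abs(tab0$delta) < 1e-12))
  expect_equal(attr(tab0, "delta_bar"), 0, tolerance = 1e-12)

  # uniform +4 degC warming with unchanged precipitation: every delta negative
  spec4 <- synthetic_spec(seed = 9, n_locations = 30L,
                          model_dT = rep(4, 11), model_dP = rep(0, 11),
                          proj_jitter = 0)
  tab4 <- fertility_change_table(b, gen_occurrence_table(spec4))
  expect_true(all(tab4$delta < 0))

  # grand mean change is the mean of the emitted delta column
  expect_equal(attr(tab4, "delta_bar"), mean(tab4$delta))
  expect_equal(attr(tab4, "f_bar"), mean(tab4$projected_fertility))
})
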