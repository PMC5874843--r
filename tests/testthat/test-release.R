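# Factor coding, effect screening, factorial regression, swelling and
# cumulative-release computations.

test_that("factor coding reproduces the published codified values digit for digit", {
  expect_equal(round(code_factor(8, 1, 48), 5), -0.70213)
  expect_equal(round(code_factor(2.44, 0, 9.1), 4), -0.4637)
  expect_equal(round(code_factor(24.5, 1, 48), 5), 0)
  expect_equal(round(code_factor(4.76, 0, 9.1), 4), 0.0462)
  expect_equal(code_factor((0 + 9.1) / 2, 0, 9.1), 0)
  expect_error(code_factor(50, 1, 48), "range")
  expect_error(code_factor(1, 5, 5), "exceed")
})

test_that("coding and decoding are exact inverses on the design range", {
  x <- seq(1, 48, length.out = 23)
  expect_equal(decode_factor(code_factor(x, 1, 48), 1, 48), x,
               tolerance = 1e-12)
  cc <- seq(-1, 1, length.out = 23)
  expect_equal(code_factor(decode_factor(cc, 0, 9.1), 0, 9.1), cc,
               tolerance = 1e-12)
})

test_that("effect screening recovers noiseless constructions and flags rank defects", {
  d <- data.frame(A = c(-1, -1, 1, 1, -1, -1, 1, 1),
                  B = c(-1, 1, -1, 1, -1, 1, -1, 1))
  d$response <- 1 + 2 * d$A
  eff <- screen_effects(d, c("A", "B", "A:B"))
  expect_equal(eff$term[1], "A")
  expect_true(eff$significant[eff$term == "A"])
  expect_equal(eff$coefficient[eff$term == "B"], 0, tolerance = 1e-12)
  expect_equal(eff$coefficient[eff$term == "A:B"], 0, tolerance = 1e-12)
  # aliased term on a rank-deficient design
  d2 <- d
  d2$C <- d2$A
  expect_error(screen_effects(d2, c("A", "C")), "alias")
})

test_that("balanced two-level designs give inclusion-invariant coefficients", {
  set.seed(5)
  d <- expand.grid(A = c(-1, 1), B = c(-1, 1))
  d <- d[rep(1:4, 3), ]
  d$response <- 2 + 1.5 * d$A - 0.8 * d$B + 0.3 * d$A * d$B +
    stats::rnorm(nrow(d), 0, 0.5)
  full <- screen_effects(d, c("A", "B", "A:B"))
  alone <- screen_effects(d, c("A", "B"))
  expect_equal(full$coefficient[full$term == "A"],
               alone$coefficient[alone$term == "A"], tolerance = 1e-10)
  expect_equal(full$coefficient[full$term == "B"],
               alone$coefficient[alone$term == "B"], tolerance = 1e-10)
})

test_that("the packaged release table shows composition significant, time not", {
  d <- release_design_table()
  expect_equal(nrow(d), 20L)
  # printed coded columns match the coding transform at printed precision
  expect_equal(d$A, round(code_factor(d$gamma_cd_pct, 0, 9.1), 4),
               tolerance = 1e-9)
  expect_equal(d$B, round(code_factor(d$time_h, 1, 48), 5), tolerance = 1e-9)
  eff <- screen_effects(d, c("A", "B", "A:B"), response = "release_pct")
  expect_true(eff$significant[eff$term == "A"])
  expect_false(eff$significant[eff$term == "B"])
  expect_equal(eff$term[1], "A")  # Pareto order puts composition first
})

test_that("reduced-model fits recover noiseless truths and handle degenerate responses", {
  d <- data.frame(A = c(-1, -1, 1, 1, 0, 0.5), B = c(-1, 1, -1, 1, 0, 0.5))
  d$response <- 3 + 4 * d$A
  fit <- fit_reduced_model(d, "A")
  expect_equal(unname(coef(fit)), c(3, 4), tolerance = 1e-12)
  expect_equal(fit$r_squared, 100, tolerance = 1e-9)
  expect_equal(predict(fit, d), d$response, tolerance = 1e-12)
  dc <- d
  dc$response <- rep(7, nrow(d))
  fit0 <- fit_reduced_model(dc, "A")
  expect_equal(unname(coef(fit0))[2], 0, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(residuals(fit0)), rep(0, nrow(dc)), tolerance = 1e-12)
})

test_that("swelling index follows the printed swollen-mass denominator", {
  expect_equal(swelling_index(2, 1), 50)
  expect_equal(swelling_index(4, 4), 0)
  expect_equal(swelling_index(4, 1), 75)
  expect_error(swelling_index(1, 2), "negative swelling")
  expect_error(swelling_index(1, 0), "positive")
})

test_that("drug content is the positive mass difference", {
  expect_equal(drug_content(58.4, 50.0), 8.4)
  expect_equal(drug_content(5, 5), 0)
  expect_error(drug_content(49, 50), "inconsistent")
})

test_that("cumulative release applies the aliquot mass balance step by step", {
  rec <- data.frame(time_h = c(1, 2, 3),
                    conc_mg_per_mL = c(0.01, 0.015, 0.018),
                    withdrawn_mL = 1, volume_mL = 5)
  # hand mass balance: m_i = c_i V + sum_{j<i} c_j v
  hand <- c(0.01 * 5,
            0.015 * 5 + 0.01 * 1,
            0.018 * 5 + 0.01 * 1 + 0.015 * 1)
  out <- cumulative_release(rec, absorbed = 0.2)
  expect_equal(out$released_mg, hand, tolerance = 1e-12)
  expect_equal(out$released_pct, hand / 0.2 * 100, tolerance = 1e-12)
  expect_true(all(diff(out$released_pct) >= 0))
  expect_false(attr(out, "overshoot"))
  # without correction only the instantaneous term remains
  out2 <- cumulative_release(rec, absorbed = 0.2, correct_sampling = FALSE)
  expect_equal(out2$released_mg, rec$conc_mg_per_mL * 5, tolerance = 1e-12)
  # single sample releasing everything reads 100%
  one <- data.frame(time_h = 1, conc_mg_per_mL = 0.04, volume_mL = 5,
                    withdrawn_mL = 1)
  expect_equal(cumulative_release(one, absorbed = 0.2)$released_pct, 100)
  # all-zero concentrations give zero release
  zero <- data.frame(time_h = 1:3, conc_mg_per_mL = 0, volume_mL = 5,
                     withdrawn_mL = 1)
  expect_equal(cumulative_release(zero, absorbed = 0.2)$released_pct,
               c(0, 0, 0))
  # overshoot flag
  big <- data.frame(time_h = 1, conc_mg_per_mL = 1, volume_mL = 5,
                    withdrawn_mL = 1)
  expect_true(attr(cumulative_release(big, absorbed = 0.2), "overshoot"))
  expect_error(cumulative_release(rec, absorbed = 0), "positive")
})

test_that("release-profile summaries recover generator ground truth", {
  cur <- make_release_curve(burst = 60, slope = 1.2, sigma = 0)
  sm <- release_profile_summary(cur, burst_window = 2,
                                late_window = c(2, max(cur$time_h)))
  expect_equal(sm$burst_pct, 60, tolerance = 0.6)
  expect_equal(sm$slope_pct_per_h, 1.2, tolerance = 0.012)
  expect_gt(sm$slope_r_squared, 0.999)
  # a pure zero-order line: burst equals slope x window
  line <- data.frame(time_h = seq(0, 10), released_pct = 2 * seq(0, 10))
  sml <- release_profile_summary(line, burst_window = 2, late_window = c(2, 10))
  expect_equal(sml$burst_pct, 4)
  expect_equal(sml$slope_pct_per_h, 2, tolerance = 1e-12)
  # a flat series has zero slope
  flat <- data.frame(time_h = seq(0, 10), released_pct = 50)
  expect_equal(release_profile_summary(flat, 2, c(2, 10))$slope_pct_per_h, 0,
               tolerance = 1e-12)
  expect_error(release_profile_summary(line, burst_window = 20), "span")
})
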