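test_that("mobile-arm cost is constant across PSA draws", {
  psa <- run_psa(psa_spec(n_draws = 2000, seed = 11))
  expect_equal(mean(psa$draws$cost_mobile), ledger_sums()$mobile_hs,
               tolerance = 1e-12)
  expect_equal(sd(psa$draws$cost_mobile), 0)
})

test_that("degenerate distributions reproduce the deterministic base case exactly", {
  spec <- psa_spec(n_draws = 50, seed = 3, clinic_cost_rel_halfwidth = 0,
                   effect_abs_halfwidth = 0, wage_cv = 0)
  psa <- run_psa(spec)
  d <- psa$draws
  expect_true(all(d$cost_in_person == psa$base$cost_in_person))
  expect_true(all(d$cost_mobile == psa$base$cost_mobile))
  expect_true(all(d$effect_mobile == 0.96))
  expect_true(all(d$effect_in_person == 0.96))
  expect_true(all(d$delta_effect == 0))
  # base-case cost saving, since the default wage mean is the ledger-implied one
  expect_equal(unique(d$delta_cost), 245.43, tolerance = 1e-9)

  plane <- icer_plane(psa)
  expect_true(all(plane$delta_effect == 0))
  expect_equal(unique(plane$delta_cost), -245.43, tolerance = 1e-9)
})

test_that("the PSA is reproducible under a fixed seed and draw order", {
  a <- run_psa(psa_spec(n_draws = 500, seed = 99))
  b <- run_psa(psa_spec(n_draws = 500, seed = 99))
  expect_identical(a$draws, b$draws)

  # different seeds agree in distribution: means within 3 standard errors
  c <- run_psa(psa_spec(n_draws = 4000, seed = 1))
  d <- run_psa(psa_spec(n_draws = 4000, seed = 2))
  se <- sqrt(sd(c$draws$cost_in_person)^2 / 4000 +
               sd(d$draws$cost_in_person)^2 / 4000)
  expect_lt(abs(mean(c$draws$cost_in_person) - mean(d$draws$cost_in_person)),
            3 * se)
})

test_that("PSA draws match an independent re-implementation of the sampler", {
  spec <- psa_spec(n_draws = 1000, seed = 123)
  psa <- run_psa(spec)

  # second, straightforward sampler: same seed policy and draw order,
  # costs assembled by plain arithmetic from the printed ledger amounts
  set.seed(123)
  n <- 1000
  clinic <- runif(n, 174.21 * 0.8, 174.21 * 1.2)
  e_mob <- pmin(pmax(runif(n, 0.94, 0.98), 0), 1)
  e_in <- pmin(pmax(runif(n, 0.94, 0.98), 0), 1)
  shape <- 1 / 0.4^2
  wage <- rgamma(n, shape = shape, rate = shape / (102.24 / 4.92))
  cost_in <- clinic + wage * 3 * 1.64 + 33.84 + 38.11 + 32.80

  expect_equal(psa$draws$cost_in_person, cost_in, tolerance = 1e-12)
  expect_equal(psa$draws$effect_mobile, e_mob, tolerance = 1e-12)
  expect_equal(psa$draws$effect_in_person, e_in, tolerance = 1e-12)
})

test_that("effect uniforms leave the mobile arm less effective in about half of draws", {
  psa <- run_psa(psa_spec(n_draws = 10000, seed = 5))
  expect_equal(mean(psa$draws$delta_effect < 0), 0.5, tolerance = 0.04)
})

test_that("CEAC fractions are frequencies of positive net benefit", {
  psa <- run_psa(psa_spec(n_draws = 2000, seed = 8))
  cv <- ceac(psa, lambda_grid = c(0, 4398.80, 20000))
  expect_true(all(cv$p_preferred >= 0 & cv$p_preferred <= 1))
  # lambda = 0 reduces to the share of cost-saving draws
  expect_equal(cv$p_preferred[cv$lambda == 0],
               mean(psa$draws$delta_cost > 0))
  # large-lambda limit: effect-improving draws plus cost-saving ties at zero
  big <- ceac(psa, lambda_grid = 1e12)$p_preferred
  expect_equal(big, mean(psa$draws$delta_effect > 0 |
                           (psa$draws$delta_effect == 0 &
                              psa$draws$delta_cost > 0)))
  expect_error(ceac(psa, lambda_grid = -1),
               class = "ambucea_validation_error")
})

test_that("CEAC is flat at one when every draw saves cost at equal effect", {
  spec <- psa_spec(n_draws = 100, seed = 4, clinic_cost_rel_halfwidth = 0.2,
                   effect_abs_halfwidth = 0, wage_cv = 0.4)
  psa <- run_psa(spec)
  expect_true(all(psa$draws$delta_effect == 0))
  expect_true(all(psa$draws$delta_cost > 0))
  cv <- ceac(psa, lambda_grid = c(0, 1000, 1e6))
  expect_true(all(cv$p_preferred == 1))
})

test_that("ICER plane quadrant counts partition the draws", {
  psa <- run_psa(psa_spec(n_draws = 3000, seed = 21))
  plane <- icer_plane(psa)
  counts <- attr(plane, "quadrant_counts")
  expect_equal(sum(counts$n_draws), 3000)
  expect_setequal(unique(plane$quadrant), counts$quadrant)
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(autoplot(ceac(psa)), "ggplot")
})

test_that("tidy and glance summarise the PSA object", {
  psa <- run_psa(psa_spec(n_draws = 300, seed = 13))
  td <- tidy(psa)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 300)
  g <- glance(psa)
  expect_equal(g$n_draws, 300)
  expect_true(g$mean_cost_in_person >= min(td$cost_in_person) &&
                g$mean_cost_in_person <= max(td$cost_in_person))
  expect_equal(g$lambda, 4398.80)
})

test_that("invalid PSA specifications are rejected", {
  expect_error(psa_spec(n_draws = 0), class = "ambucea_validation_error")
  expect_error(psa_spec(wage_mean = 0), class = "ambucea_validation_error")
  expect_error(psa_spec(wage_cv = -0.1), class = "ambucea_validation_error")
  expect_error(psa_spec(effect_abs_halfwidth = -1),
               class = "ambucea_validation_error")
})
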