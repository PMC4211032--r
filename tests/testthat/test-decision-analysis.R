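test_that("per-effect willingness to pay is the per-QALY threshold times the decrement", {
  expect_equal(wtp_per_effect(109970, 0.04), 4398.80)
  expect_equal(wtp_per_effect(123456, 0), 0)
  expect_equal(wtp_per_effect(100000, 0.04), 4000)
  expect_error(wtp_per_effect(0, 0.04), class = "ambucea_validation_error")
})

test_that("incremental comparison recovers the base-case cost differences", {
  bd <- aggregate_costs(default_cost_components())
  s <- ledger_sums()

  soc <- incremental(bd, default_effects(), perspective = "societal")
  expect_equal(soc$delta_cost, s$in_person_hs + s$in_person_patient - s$mobile_hs,
               tolerance = 1e-12)
  expect_equal(round_half_up(soc$delta_cost), 245)
  expect_equal(soc$delta_effect, 0)

  hs <- incremental(bd, default_effects(), perspective = "health_system")
  expect_equal(round_half_up(hs$delta_cost), 38)

  # identical arms compare to (0, 0)
  same <- bd
  same[same$arm == "in_person", c("health_system", "patient", "external", "total")] <-
    same[same$arm == "mobile", c("health_system", "patient", "external", "total")]
  comp0 <- incremental(same, default_effects())
  expect_equal(comp0$delta_cost, 0)
  expect_equal(comp0$delta_effect, 0)

  td <- tidy(soc)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$perspective, "societal")
})

test_that("the ICER is flagged not reportable at zero effect difference", {
  base <- incremental(aggregate_costs(default_cost_components()))
  got <- icer(base)
  expect_false(got$reportable)
  expect_true(is.na(got$icer))
  expect_equal(got$quadrant, "dominant")  # equal effect, strictly cheaper

  # cheaper and more effective: ICER is the negative ratio, dominant
  dom <- icer(make_comparison(delta_cost = 43.99, delta_effect = 0.01))
  expect_true(dom$reportable)
  expect_equal(dom$icer, -4399)
  expect_equal(dom$quadrant, "dominant")

  zero_cost <- icer(make_comparison(delta_cost = 0, delta_effect = 0.5))
  expect_equal(zero_cost$icer, 0)
})

test_that("ICER quadrant labels agree with a brute-force sign check", {
  grid <- expand.grid(saving = c(-50, 0, 50), effect = c(-0.1, 0, 0.1))
  for (i in seq_len(nrow(grid))) {
    comp <- make_comparison(grid$saving[i], grid$effect[i])
    got <- icer(comp)$quadrant
    inc <- -grid$saving[i]
    de <- grid$effect[i]
    # independent enumeration of the plane quadrants
    want <- if (de == 0 && inc == 0) "equivalent"
    else if (de >= 0 && inc <= 0) "dominant"
    else if (de <= 0 && inc >= 0) "dominated"
    else if (de > 0 && inc > 0) "trade_off_more_effective_more_costly"
    else "trade_off_less_effective_less_costly"
    expect_equal(got, want, info = sprintf("saving=%g effect=%g",
                                           grid$saving[i], grid$effect[i]))
  }
})

test_that("incremental net benefit is affine in lambda with slope delta-effect", {
  set.seed(42)
  for (i in 1:10) {
    comp <- make_comparison(runif(1, -300, 300), runif(1, -0.2, 0.2))
    lam <- sort(runif(3, 0, 20000))
    v <- inb(comp, lam)$inb
    # three-point collinearity
    slope1 <- (v[2] - v[1]) / (lam[2] - lam[1])
    slope2 <- (v[3] - v[2]) / (lam[3] - lam[2])
    expect_equal(slope1, slope2, tolerance = 1e-9)
    expect_equal(slope1, comp$delta_effect, tolerance = 1e-9)
    expect_equal(inb(comp, 0)$inb, comp$delta_cost)
  }

  # hand arithmetic: 4398.80 x (-0.02) + 198.69
  comp <- make_comparison(198.69, -0.02)
  expect_equal(inb(comp, 4398.80)$inb, 110.714, tolerance = 1e-9)
})

test_that("zero effect difference makes the INB lambda-invariant", {
  comp <- incremental(aggregate_costs(default_cost_components()))
  expect_equal(comp$delta_effect, 0)
  set.seed(7)
  lam <- c(0, runif(25, 0, 1e7))
  v <- inb(comp, lam)$inb
  expect_true(all(v == comp$delta_cost))
  expect_equal(round_half_up(unique(v)), 245)
})

test_that("USD presentation applies the exchange rate with half-up rounding", {
  expect_equal(to_usd(245, rate = 0.9102, whole_dollars = TRUE), 223)
  expect_equal(to_usd(38, rate = 0.9102, whole_dollars = TRUE), 35)
  expect_equal(to_usd(0, rate = 0.9102), 0)
  expect_equal(to_usd(100, rate = 0.5), 50)
  expect_error(to_usd(100, rate = 0), class = "ambucea_validation_error")
})

test_that("base_case summarises both perspectives consistently", {
  bc <- base_case()
  expect_equal(nrow(bc), 2)
  expect_equal(bc$perspective, c("societal", "health_system"))
  expect_false(any(bc$icer_reportable))
  expect_equal(bc$inb, bc$delta_cost_cad)  # zero effect difference
  expect_equal(round_half_up(bc$delta_cost_usd), c(223, 35))
})
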