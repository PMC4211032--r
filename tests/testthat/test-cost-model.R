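test_that("ledger aggregation reproduces the base-case subtotals", {
  bd <- aggregate_costs(default_cost_components())
  s <- ledger_sums()

  mob <- dplyr::filter(bd, arm == "mobile")
  ip <- dplyr::filter(bd, arm == "in_person")
  expect_equal(mob$health_system, s$mobile_hs, tolerance = 1e-12)
  expect_equal(ip$health_system, s$in_person_hs, tolerance = 1e-12)
  expect_equal(ip$patient, s$in_person_patient, tolerance = 1e-12)
  expect_equal(ip$total, s$in_person_hs + s$in_person_patient,
               tolerance = 1e-12)
  expect_equal(mob$external, 0)

  # presentation rounding matches the printed whole-dollar subtotals
  expect_equal(round_half_up(c(mob$health_system, ip$health_system,
                               ip$patient, ip$total)),
               c(136, 174, 207, 381))
})

test_that("an arm with no components aggregates to all-zero subtotals", {
  empty <- default_cost_components()[0, ]
  bd <- aggregate_costs(empty, arms = "mobile")
  expect_equal(nrow(bd), 1L)
  expect_equal(unlist(bd[c("health_system", "patient", "external", "total")]),
               c(health_system = 0, patient = 0, external = 0, total = 0))
})

test_that("aggregation is permutation-invariant and additive under splits", {
  base <- aggregate_costs(default_cost_components())
  for (seed in 1:5) {
    set.seed(seed)
    comp <- default_cost_components()
    shuffled <- comp[sample(nrow(comp)), ]
    expect_equal(dplyr::arrange(aggregate_costs(shuffled), arm),
                 dplyr::arrange(base, arm))

    # split one random component into two parts with the same sum
    i <- sample(nrow(comp), 1)
    frac <- runif(1)
    part <- comp[i, ]
    comp$amount[i] <- part$amount * frac
    part$amount <- part$amount * (1 - frac)
    part$label <- paste(part$label, "(remainder)")
    split_ledger <- dplyr::bind_rows(comp, part)
    expect_equal(dplyr::arrange(aggregate_costs(split_ledger), arm),
                 dplyr::arrange(base, arm),
                 tolerance = 1e-12)
  }
})

test_that("invalid ledgers are rejected with validation errors", {
  comp <- default_cost_components()
  neg <- comp
  neg$amount[1] <- -1
  expect_error(aggregate_costs(neg), class = "ambucea_validation_error")

  dup <- dplyr::bind_rows(comp, comp[1, ])
  expect_error(aggregate_costs(dup), class = "ambucea_validation_error")

  bad_payer <- comp
  bad_payer$payer[1] <- "insurer"
  expect_error(aggregate_costs(bad_payer), class = "ambucea_validation_error")

  expect_error(aggregate_costs(comp[, -5]), class = "ambucea_validation_error")
})

test_that("in-person patient cost sums leisure, caregiver, travel, parking", {
  p <- econ_params()

  expect_equal(patient_cost_in_person(wage = 25, params = p, visits = 0,
                                      caregiver_first_visit = FALSE), 0)

  # one visit at the homemaker wage, caregiver present, hand-summed
  got <- patient_cost_in_person(wage = 11.28, params = p, visits = 1,
                                caregiver_first_visit = TRUE,
                                round_trip_km = 152, detail = TRUE)
  expect_equal(got$leisure, 11.28 * 3)
  expect_equal(got$caregiver, 11.28 * 3)
  expect_equal(got$travel, 152 * p$travel_cost_per_km)
  expect_equal(got$parking, 20)
  expect_equal(got$total, 11.28 * 3 + 11.28 * 3 + 152 * p$travel_cost_per_km + 20)

  # base-case calibration: implied mean wage over 1.64 visits gives the
  # published patient subtotal
  total <- patient_cost_in_person(wage = 102.24 / (1.64 * 3), params = p,
                                  visits = 1.64, caregiver_first_visit = TRUE,
                                  round_trip_km = 152)
  expect_equal(total, 206.99, tolerance = 1e-6)
})

test_that("in-person patient cost is linear in visits and increasing in wage", {
  p <- econ_params()
  for (wage in c(0, 11.28, 26.71)) {
    f <- function(v) patient_cost_in_person(wage, p, visits = v,
                                            caregiver_first_visit = FALSE,
                                            round_trip_km = 120)
    expect_equal(f(2), 2 * f(1), tolerance = 1e-12)
    expect_equal(f(3.5) - f(2.5), f(1), tolerance = 1e-12)
  }
  w <- c(5, 10, 20, 40)
  costs <- patient_cost_in_person(w, p, visits = 1.64,
                                  caregiver_first_visit = TRUE)
  expect_true(all(diff(costs) > 0))
  expect_error(patient_cost_in_person(-1, p),
               class = "ambucea_validation_error")
})

test_that("mobile patient data cost is computed but ruled negligible", {
  got <- patient_cost_mobile(n_submissions = 18)
  # 18 submissions x 0.35 MB at $45 per 2 GB, computed independently
  expect_equal(got$data_cost, 18 * 0.35 * (45 / 2) / 1024, tolerance = 1e-12)
  expect_lt(got$data_cost, 0.15)
  expect_true(got$negligible)
  expect_equal(got$leisure_cost, 0)
  expect_equal(got$ledger_amount, 0)

  expect_equal(patient_cost_mobile(n_submissions = 0)$data_cost, 0)

  strict <- patient_cost_mobile(n_submissions = 18, strict = TRUE)
  expect_equal(strict$ledger_amount, strict$data_cost)
})

test_that("start-up costs amortize over patients served in the lifespan", {
  # inverse of the ledger's fixed rows: 5000 x (1.39 + 6.94 + 0.44)
  expect_equal(amortize_fixed(5000 * (1.39 + 6.94 + 0.44)), 8.77)
  expect_equal(amortize_fixed(0), 0)
  # halved uptake doubles the per-patient share
  half <- econ_params(patients_per_year = 500)
  expect_equal(amortize_fixed(1000, half), 2 * amortize_fixed(1000))
  expect_error(econ_params(patients_per_year = 0),
               class = "ambucea_validation_error")
  expect_error(amortize_fixed(-5), class = "ambucea_validation_error")
})
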