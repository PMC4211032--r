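#' Per-visit decomposition of the in-person arm
#'
#' Splits the in-person ledger into the pieces the deterministic and
#' probabilistic sensitivity analyses rescale: the health-system subtotal
#' (assumed to scale linearly with visit count, i.e. subtotal / 1.64 per
#' visit), per-visit patient leisure, travel and parking, and the one-off
#' caregiver cost tied to the first visit. Patient rows are recognised by
#' label (leisure / caregiver / travel / parking).
#'
#' @param components Cost ledger.
#' @param params An [econ_params()] object.
#' @param arm Name of the in-person arm in the ledger.
#' @return One-row tibble: `hs_subtotal`, `hs_per_visit`,
#'   `leisure_per_visit`, `travel_per_visit`, `parking_per_visit`,
#'   `caregiver_first_visit`, plus the ledger totals `leisure_total`,
#'   `travel_total`, `parking_total`.
#' @export
per_visit_costs <- function(components = default_cost_components(),
                            params = econ_params(),
                            arm = "in_person") {
  params <- as_econ_params(params)
  components <- cost_components(components)
  v <- params$visits_per_month
  ip <- dplyr::filter(components, .data$arm == !!arm)
  if (nrow(ip) == 0) stop_validation("Arm `%s` not found in ledger.", arm)
  hs <- sum(ip$amount[ip$payer == "health_system"])
  patient <- dplyr::filter(ip, .data$payer == "patient")
  pick <- function(pattern) {
    hit <- grepl(pattern, patient$label, ignore.case = TRUE)
    if (sum(hit) > 1) stop_validation("Ambiguous patient row for '%s'.", pattern)
    if (!any(hit)) 0 else patient$amount[hit]
  }
  leisure <- pick("leisure")
  caregiver <- pick("caregiver")
  travel <- pick("travel")
  parking <- pick("parking")
  matched <- leisure + caregiver + travel + parking
  if (abs(matched - sum(patient$amount)) > 1e-8) {
    stop_validation(
      "Unrecognised patient cost rows in arm `%s`; labels must identify leisure, caregiver, travel and parking.",
      arm)
  }
  tibble::tibble(
    hs_subtotal = hs,
    hs_per_visit = hs / v,
    leisure_per_visit = leisure / v,
    travel_per_visit = travel / v,
    parking_per_visit = parking / v,
    caregiver_first_visit = caregiver,
    leisure_total = leisure,
    travel_total = travel,
    parking_total = parking
  )
}

in_person_cost_at <- function(pv, visits, include_caregiver = visits > 0) {
  per_visit <- pv$hs_per_visit + pv$leisure_per_visit +
    pv$travel_per_visit + pv$parking_per_visit
  per_visit * visits + ifelse(include_caregiver, pv$caregiver_first_visit, 0)
}

#' Scenario analysis: fewer in-person visits and mobile-arm crossover
#'
#' Recomputes the societal comparison with the in-person arm costed at an
#' arbitrary visit count (all per-visit costs scale linearly; the
#' caregiver attends only the first visit, so that cost is a one-off) and
#' with a fraction of mobile-arm patients crossing over to one in-person
#' visit. The crossover visit is costed at the per-visit marginal rate —
#' health-system, leisure, travel and parking — without the caregiver,
#' which the model treats as a one-off of the conventional pathway rather
#' than a per-visit cost; `crossover_caregiver = TRUE` adds it.
#'
#' @param visits In-person arm visit count over the horizon (>= 0).
#' @param crossover_fraction Fraction of mobile patients who also attend
#'   one in-person visit, in `[0, 1]`.
#' @param components Cost ledger.
#' @param effects Named success probabilities per arm.
#' @param params An [econ_params()] object.
#' @param crossover_caregiver Cost the crossover visit with a caregiver.
#' @return A `cea_comparison` (societal perspective).
#' @export
#' @examples
#' scenario_visits(visits = 1)           # one in-person visit
#' scenario_visits(crossover_fraction = 1)  # all mobile patients attend once
scenario_visits <- function(visits = econ_params()$visits_per_month,
                            crossover_fraction = 0,
                            components = default_cost_components(),
                            effects = default_effects(),
                            params = econ_params(),
                            crossover_caregiver = FALSE) {
  params <- as_econ_params(params)
  check_scalar_number(visits, "visits", min = 0)
  check_probability(crossover_fraction, "crossover_fraction")
  pv <- per_visit_costs(components, params)
  breakdown <- aggregate_costs(components)
  cost_mobile <- breakdown$total[breakdown$arm == "mobile"]
  cost_in <- in_person_cost_at(pv, visits)
  one_visit <- in_person_cost_at(pv, 1, include_caregiver = crossover_caregiver)
  cost_mobile <- cost_mobile + crossover_fraction * one_visit
  new_comparison(
    delta_cost = cost_in - cost_mobile,
    delta_effect = effects[["mobile"]] - effects[["in_person"]],
    perspective = "societal"
  )
}

#' Two-way sensitivity analysis: leisure cost by mobile effectiveness
#'
#' Builds the grid of incremental net benefit over per-visit patient
#' leisure cost (columns: 3 h x hourly wage, so $33.84 for the homemaker
#' wage up to $80.12 for the age/sex-adjusted wage) and mobile success
#' rate (rows, 0.90-0.96), holding the in-person reference effect at
#' 0.96. Each cell is
#' `lambda * (effect - reference) + (C_in_person(L) - C_mobile)` with
#' total leisure scaling by 1.64 visits while the caregiver, travel and
#' parking totals stay at their ledger values. Negative cells favor
#' in-person follow-up.
#'
#' @param leisure_axis Per-visit leisure cost values, CAD.
#' @param effect_axis Mobile success probabilities.
#' @param components Cost ledger.
#' @param params An [econ_params()] object.
#' @param reference_effect In-person success probability (default 0.96,
#'   calibrated so the top row of the grid is the pure cost difference).
#' @return A `cea_twoway` tibble (long form: `mobile_effect`,
#'   `leisure_cost_per_visit`, `inb`) with attributes `lambda` and
#'   `reference_effect`. Plot with [autoplot.cea_twoway()].
#' @export
#' @examples
#' two_way()
two_way <- function(leisure_axis = c(33.84, 56.98, 80.12),
                    effect_axis = c(0.96, 0.94, 0.92, 0.90),
                    components = default_cost_components(),
                    params = econ_params(),
                    reference_effect = 0.96) {
  params <- as_econ_params(params)
  if (length(leisure_axis) == 0 || length(effect_axis) == 0) {
    stop_validation("Axes must be non-empty.")
  }
  if (any(leisure_axis < 0)) stop_validation("Leisure costs must be >= 0.")
  for (e in effect_axis) check_probability(e, "effect_axis")
  check_probability(reference_effect, "reference_effect")

  lambda <- wtp_per_effect(params$wtp_per_qaly, params$qaly_loss_per_complication)
  pv <- per_visit_costs(components, params)
  breakdown <- aggregate_costs(components)
  cost_mobile <- breakdown$total[breakdown$arm == "mobile"]
  cost_in <- function(L) {
    pv$hs_subtotal + params$visits_per_month * L +
      pv$caregiver_first_visit + pv$travel_total + pv$parking_total
  }
  grid <- tidyr::expand_grid(mobile_effect = effect_axis,
                             leisure_cost_per_visit = leisure_axis) |>
    dplyr::mutate(
      inb = lambda * (.data$mobile_effect - reference_effect) +
        cost_in(.data$leisure_cost_per_visit) - cost_mobile
    )
  structure(grid,
            lambda = lambda,
            reference_effect = reference_effect,
            class = c("cea_twoway", class(grid)))
}
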