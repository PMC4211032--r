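#' Validate a cost-component ledger
#'
#' A cost ledger is a tidy tibble with one row per cost component:
#' columns `arm` (character), `label` (character, unique within an arm),
#' `payer` (one of `"health_system"`, `"patient"`, `"external"`),
#' `kind` (`"fixed"` or `"variable"`), and `amount` (CAD per patient per
#' 30-day horizon, non-negative, held unrounded).
#'
#' @param x A data frame of components.
#' @return The validated ledger as a tibble.
#' @export
#' @examples
#' cost_components(default_cost_components())
cost_components <- function(x) {
  required <- c("arm", "label", "payer", "kind", "amount")
  if (!is.data.frame(x)) stop_validation("Components must be a data frame.")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_validation("Components are missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[required]
  if (nrow(x) > 0) {
    bad_payer <- setdiff(unique(x$payer), payer_levels)
    if (length(bad_payer) > 0) {
      stop_validation("Unknown payer stratum: %s",
                      paste(bad_payer, collapse = ", "))
    }
    bad_kind <- setdiff(unique(x$kind), kind_levels)
    if (length(bad_kind) > 0) {
      stop_validation("Unknown cost kind: %s", paste(bad_kind, collapse = ", "))
    }
    if (!is.numeric(x$amount) || any(!is.finite(x$amount))) {
      stop_validation("Component amounts must be finite numbers.")
    }
    if (any(x$amount < 0)) {
      stop_validation("Component amounts must be non-negative.")
    }
    dup <- x |>
      dplyr::count(.data$arm, .data$label) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop_validation("Duplicate component label within an arm: %s",
                      paste(dup$label, collapse = ", "))
    }
  }
  x
}

#' Base-case cost ledger for both follow-up arms
#'
#' The per-patient 30-day micro-costing ledger of the model's base case:
#' the conventional in-person arm costed at 1.64 attended visits
#' (health-system clinic costs plus patient leisure, caregiver, travel and
#' parking) and the mobile-app arm costed for 30 days of monitoring under a
#' bring-your-own-device model (amortized start-up costs plus licensing,
#' support, hosting, and the e-assessment surgeon fee). Mobile-arm
#' patient-borne costs (a few cents of data, no interrupted leisure) are
#' negligible and carried outside this ledger; see [patient_cost_mobile()].
#'
#' @return A cost ledger tibble (see [cost_components()]).
#' @export
#' @examples
#' aggregate_costs(default_cost_components())
default_cost_components <- function() {
  tibble::tribble(
    ~arm,        ~label,                          ~payer,          ~kind,      ~amount,
    "in_person", "Compensation",                  "health_system", "fixed",    103.74,
    "in_person", "Equipment",                     "health_system", "fixed",    2.16,
    "in_person", "Drugs",                         "health_system", "variable", 0.21,
    "in_person", "Other (linens)",                "health_system", "variable", 3.83,
    "in_person", "Clinical assistant (10 min)",   "health_system", "variable", 10.25,
    "in_person", "Surgeon fee",                   "health_system", "variable", 43.46,
    "in_person", "Resident",                      "health_system", "variable", 10.56,
    "in_person", "Patient leisure time",          "patient",       "variable", 102.24,
    "in_person", "Caregiver wage",                "patient",       "variable", 33.84,
    "in_person", "Travel (to and from clinic)",   "patient",       "variable", 38.11,
    "in_person", "Parking",                       "patient",       "variable", 32.80,
    "mobile",    "Health centre setup",           "health_system", "fixed",    1.39,
    "mobile",    "Design/setup procedure protocols", "health_system", "fixed", 6.94,
    "mobile",    "Staff training",                "health_system", "fixed",    0.44,
    "mobile",    "Platform licensing, accounts",  "health_system", "variable", 42.00,
    "mobile",    "Standard support",              "health_system", "variable", 43.05,
    "mobile",    "Infrastructure hosting",        "health_system", "variable", 19.95,
    "mobile",    "Surgeon fee",                   "health_system", "variable", 22.00
  )
}

#' Base-case 30-day success probabilities per arm
#'
#' Effectiveness is the probability of a successful surgical outcome at 30
#' days (no intervention required for the original surgery). The base case
#' models equivalence between arms: both at 0.96, consistent with the
#' roughly 5% complication rate in ambulatory breast reconstruction and
#' with the upper end of the effect range explored in the two-way
#' sensitivity analysis.
#'
#' @return Named numeric vector with elements `mobile` and `in_person`.
#' @export
default_effects <- function() {
  c(mobile = 0.96, in_person = 0.96)
}

#' Aggregate a cost ledger by payer stratum
#'
#' Sums component amounts by arm and payer and appends the societal total
#' (health-system + patient + external subtotals). Values are left
#' unrounded; rounding happens only in the report layer.
#'
#' @param components A cost ledger (see [cost_components()]).
#' @param arms Character vector of arms to report. Defaults to the arms
#'   present in `components`; pass explicitly to include an arm with no
#'   components (all-zero subtotals).
#' @return A tibble with one row per arm and columns `arm`,
#'   `health_system`, `patient`, `external`, `total`.
#' @export
#' @examples
#' aggregate_costs(default_cost_components())
aggregate_costs <- function(components, arms = NULL) {
  components <- cost_components(components)
  arms <- arms %||% unique(components$arm)
  wide <- components |>
    dplyr::filter(.data$arm %in% arms) |>
    dplyr::count(.data$arm, .data$payer, wt = .data$amount, name = "subtotal") |>
    tidyr::pivot_wider(names_from = "payer", values_from = "subtotal",
                       values_fill = 0)
  skeleton <- tibble::tibble(arm = arms)
  for (p in payer_levels) {
    if (!p %in% names(wide)) wide[[p]] <- numeric(nrow(wide))
  }
  skeleton |>
    dplyr::left_join(wide, by = "arm") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(payer_levels),
                                ~ tidyr::replace_na(.x, 0))) |>
    dplyr::mutate(total = .data$health_system + .data$patient + .data$external)
}

#' Patient-borne cost of in-person follow-up
#'
#' Sums the four patient-side cost streams of attending clinic in person:
#' foregone leisure (wage x leisure hours per visit x visits), a caregiver
#' at the first visit only (caregiver wage x leisure hours, once), travel
#' (round-trip km x per-km rate x visits), and parking (per-visit rate x
#' visits). Vectorized over `wage`, `visits`, `round_trip_km` and
#' `caregiver_first_visit`.
#'
#' @param wage Patient hourly wage, CAD/h (>= 0).
#' @param params An [econ_params()] object.
#' @param visits Number of visits attended over the horizon (>= 0, may be
#'   fractional for cohort means).
#' @param caregiver_first_visit Logical; caregiver present at the first
#'   visit. The caregiver cost is a one-off: it does not scale with visits
#'   and is zero when `visits == 0`.
#' @param round_trip_km Round-trip driving distance per visit, km.
#' @param detail If `TRUE`, return a tibble of the four addends plus the
#'   total instead of the total alone.
#' @return Numeric vector of total patient cost (CAD), or a tibble when
#'   `detail = TRUE`.
#' @export
#' @examples
#' patient_cost_in_person(wage = 11.28, visits = 1, round_trip_km = 152)
patient_cost_in_person <- function(wage,
                                   params = econ_params(),
                                   visits = params$visits_per_month,
                                   caregiver_first_visit = TRUE,
                                   round_trip_km = 152,
                                   detail = FALSE) {
  params <- as_econ_params(params)
  if (!is.numeric(wage) || any(!is.finite(wage)) || any(wage < 0)) {
    stop_validation("`wage` must be non-negative and finite.")
  }
  if (!is.numeric(visits) || any(!is.finite(visits)) || any(visits < 0)) {
    stop_validation("`visits` must be non-negative and finite.")
  }
  if (any(round_trip_km < 0)) {
    stop_validation("`round_trip_km` must be non-negative.")
  }
  leisure <- wage * params$leisure_hours_per_visit * visits
  caregiver <- ifelse(caregiver_first_visit & visits > 0,
                      params$caregiver_hourly_wage * params$leisure_hours_per_visit,
                      0)
  travel <- round_trip_km * params$travel_cost_per_km * visits
  parking <- params$parking_per_visit * visits
  total <- leisure + caregiver + travel + parking
  if (detail) {
    tibble::tibble(leisure = leisure, caregiver = caregiver,
                   travel = travel, parking = parking, total = total)
  } else {
    total
  }
}

#' Patient-borne cost of mobile-app follow-up
#'
#' The only patient-side resource in the bring-your-own-device mobile arm
#' is cellular data: each submission (questionnaire plus photo) uses about
#' 0.35 MB and data costs about $22.50/GB, so a full month of monitoring
#' costs around 14 cents. Foregone leisure is zero by design: submissions
#' do not interrupt leisure. The data cost is computed and reported but
#' classified negligible and excluded from the societal ledger in the base
#' accounting; set `strict = TRUE` for a strict-accounting mode that
#' carries it into `ledger_amount`.
#'
#' @param params An [econ_params()] object.
#' @param n_submissions Number of submissions over the horizon (default
#'   18: daily for two weeks then weekly for two weeks).
#' @param strict Include the data cost in `ledger_amount` instead of
#'   treating it as negligible.
#' @param negligible_below Threshold (CAD) under which the cost is flagged
#'   negligible.
#' @return One-row tibble: `n_submissions`, `data_cost`, `leisure_cost`
#'   (always 0), `negligible`, `ledger_amount`.
#' @export
#' @examples
#' patient_cost_mobile()
patient_cost_mobile <- function(params = econ_params(),
                                n_submissions = 18,
                                strict = FALSE,
                                negligible_below = 1) {
  params <- as_econ_params(params)
  check_scalar_number(n_submissions, "n_submissions", min = 0)
  data_cost <- n_submissions * params$data_mb_per_submission *
    params$data_price_per_gb / 1024
  negligible <- data_cost < negligible_below
  tibble::tibble(
    n_submissions = n_submissions,
    data_cost = data_cost,
    leisure_cost = 0,
    negligible = negligible,
    ledger_amount = if (strict) data_cost else 0
  )
}

#' Amortize start-up costs over the technology lifespan
#'
#' Mobile-arm start-up costs (health-centre setup, protocol design,
#' training) are one-time outlays divided over all patients served during
#' the useful lifespan of smartphone technology.
#'
#' @param total_fixed Total one-time start-up cost, CAD (>= 0).
#' @param params An [econ_params()] object supplying `patients_per_year`
#'   and `amortization_years`.
#' @return Per-patient fixed cost, CAD.
#' @export
#' @examples
#' amortize_fixed(43850)  # 8.77 per patient at 1000/yr over 5 yr
amortize_fixed <- function(total_fixed, params = econ_params()) {
  params <- as_econ_params(params)
  check_scalar_number(total_fixed, "total_fixed", min = 0)
  denom <- params$patients_per_year * params$amortization_years
  if (denom == 0) stop_validation("Amortization denominator is zero.")
  total_fixed / denom
}
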