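#' Convert a per-QALY threshold to a per-effect willingness to pay
#'
#' The model's effect unit is one successful 30-day surgical outcome; the
#' value of avoiding the typical complication (a superficial skin
#' infection, 0.04 QALY) converts a per-QALY threshold into a per-effect
#' willingness to pay: $109,970/QALY x 0.04 QALY = $4398.80 per effect.
#'
#' @param wtp_per_qaly Willingness to pay per QALY, CAD (> 0).
#' @param qaly_loss QALY decrement per complication (>= 0).
#' @return Willingness to pay per effect, CAD.
#' @export
#' @examples
#' wtp_per_effect(109970, 0.04)
wtp_per_effect <- function(wtp_per_qaly, qaly_loss) {
  check_scalar_number(wtp_per_qaly, "wtp_per_qaly", min = 0, strict_min = TRUE)
  check_scalar_number(qaly_loss, "qaly_loss", min = 0)
  wtp_per_qaly * qaly_loss
}

new_comparison <- function(delta_cost, delta_effect, perspective,
                           intervention = "mobile", comparator = "in_person") {
  structure(
    list(
      delta_cost = delta_cost,      # comparator - intervention: cost saving
      delta_effect = delta_effect,  # intervention - comparator
      perspective = perspective,
      intervention = intervention,
      comparator = comparator,
      orientation = "cost saving (comparator minus intervention); effect (intervention minus comparator)"
    ),
    class = "cea_comparison"
  )
}

#' Incremental cost and effect between the two arms
#'
#' Computes the pairwise comparison of the mobile (intervention) and
#' in-person (comparator) arms under a payer perspective. `delta_cost` is
#' oriented as a cost *saving* (comparator minus intervention: positive
#' means the intervention is cheaper); `delta_effect` is intervention
#' minus comparator. Under the societal perspective all payer strata
#' enter; under the health-system perspective only health-system costs do.
#'
#' @param breakdown Output of [aggregate_costs()]: one row per arm.
#' @param effects Named numeric vector of 30-day success probabilities,
#'   with names matching the arms.
#' @param perspective `"societal"` or `"health_system"`.
#' @param intervention,comparator Arm names in `breakdown`.
#' @return A `cea_comparison` object; see [tidy.cea_comparison()].
#' @export
#' @examples
#' aggregate_costs(default_cost_components()) |>
#'   incremental(default_effects(), perspective = "societal")
incremental <- function(breakdown, effects = default_effects(),
                        perspective = c("societal", "health_system"),
                        intervention = "mobile", comparator = "in_person") {
  perspective <- match.arg(perspective)
  needed <- c(intervention, comparator)
  if (!all(needed %in% breakdown$arm)) {
    stop_validation("`breakdown` must contain arms: %s",
                    paste(needed, collapse = ", "))
  }
  if (!all(needed %in% names(effects))) {
    stop_validation("`effects` must be named for arms: %s",
                    paste(needed, collapse = ", "))
  }
  for (e in needed) check_probability(effects[[e]], paste0("effects[", e, "]"))
  col <- if (perspective == "societal") "total" else "health_system"
  cost_of <- function(a) breakdown[[col]][breakdown$arm == a]
  new_comparison(
    delta_cost = cost_of(comparator) - cost_of(intervention),
    delta_effect = effects[[intervention]] - effects[[comparator]],
    perspective = perspective,
    intervention = intervention,
    comparator = comparator
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s (%s perspective)\n",
              x$intervention, x$comparator, x$perspective))
  cat(sprintf("  cost saving (%s - %s): $%.2f CAD\n",
              x$comparator, x$intervention, x$delta_cost))
  cat(sprintf("  effect difference (%s - %s): %.4f\n",
              x$intervention, x$comparator, x$delta_effect))
  invisible(x)
}

#' @rdname incremental
#' @param x A `cea_comparison` object.
#' @param ... Unused.
#' @export
tidy.cea_comparison <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention,
    comparator = x$comparator,
    perspective = x$perspective,
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect
  )
}

quadrant_label <- function(cost_increment, delta_effect, tol = 1e-9) {
  de <- ifelse(abs(delta_effect) < tol, 0, sign(delta_effect))
  dc <- ifelse(abs(cost_increment) < tol, 0, sign(cost_increment))
  dplyr::case_when(
    de == 0 & dc == 0 ~ "equivalent",
    de >= 0 & dc <= 0 ~ "dominant",
    de <= 0 & dc >= 0 ~ "dominated",
    de > 0 & dc > 0 ~ "trade_off_more_effective_more_costly",
    TRUE ~ "trade_off_less_effective_less_costly"
  )
}

#' Incremental cost-effectiveness ratio with the not-reportable rule
#'
#' The ICER is the conventional ratio (C_intervention - C_comparator) /
#' (E_intervention - E_comparator). When the effect difference is zero —
#' the model's base case, where follow-up modality does not change the
#' complication rate — the ratio is undefined and flagged not reportable
#' rather than raising an error; the cost-effectiveness quadrant label is
#' attached in every case.
#'
#' @param comp A `cea_comparison` from [incremental()] or
#'   [scenario_visits()].
#' @param tol Effect differences smaller than this in absolute value are
#'   treated as exactly zero (default 1e-9).
#' @return One-row tibble: `icer` (NA when not reportable), `reportable`,
#'   `quadrant`, `delta_cost` (intervention minus comparator),
#'   `delta_effect`.
#' @export
#' @examples
#' comp <- aggregate_costs(default_cost_components()) |> incremental()
#' icer(comp)  # delta-effect 0: not reportable
icer <- function(comp, tol = 1e-9) {
  stopifnot(inherits(comp, "cea_comparison"))
  increment <- -comp$delta_cost
  reportable <- abs(comp$delta_effect) >= tol
  tibble::tibble(
    icer = if (reportable) increment / comp$delta_effect else NA_real_,
    reportable = reportable,
    quadrant = quadrant_label(increment, comp$delta_effect, tol),
    delta_cost = increment,
    delta_effect = comp$delta_effect
  )
}

#' Incremental net benefit
#'
#' INB(lambda) = lambda x delta_effect + delta_cost_saving: affine in the
#' willingness to pay with slope equal to the effect difference and
#' intercept equal to the cost saving. Positive values favor the
#' intervention (mobile follow-up). When the effect difference is exactly
#' zero the INB equals the cost saving at every willingness to pay, which
#' is why the base case reports INB = $245 regardless of lambda.
#'
#' @param comp A `cea_comparison`.
#' @param lambda Willingness to pay per effect, CAD (vectorized, >= 0).
#' @return Tibble with columns `lambda` and `inb`.
#' @export
#' @examples
#' comp <- aggregate_costs(default_cost_components()) |> incremental()
#' inb(comp, lambda = c(0, 4398.80, 1e6))
inb <- function(comp, lambda) {
  stopifnot(inherits(comp, "cea_comparison"))
  if (any(lambda < 0)) stop_validation("`lambda` must be non-negative.")
  tibble::tibble(
    lambda = lambda,
    inb = lambda * comp$delta_effect + comp$delta_cost
  )
}

#' Present a CAD amount in USD
#'
#' Multiplies by the USD-per-CAD rate. Unrounded by default; rounding to
#' whole dollars is presentation-layer behaviour (`whole_dollars = TRUE`
#' uses half-up rounding).
#'
#' @param amount_cad Amount in CAD (vectorized).
#' @param rate USD per CAD (> 0). The default is the presentation rate in
#'   [econ_params()].
#' @param whole_dollars Round half-up to whole dollars.
#' @return Amount in USD.
#' @export
#' @examples
#' to_usd(245, whole_dollars = TRUE)
to_usd <- function(amount_cad, rate = econ_params()$exchange_rate_usd_per_cad,
                   whole_dollars = FALSE) {
  check_scalar_number(rate, "rate", min = 0, strict_min = TRUE)
  out <- amount_cad * rate
  if (whole_dollars) round_half_up(out) else out
}

#' Base-case decision summary for both perspectives
#'
#' Convenience wrapper: aggregates the ledger, forms the societal and
#' health-system comparisons, and reports cost saving (CAD and USD), the
#' ICER flag, and the INB at the per-effect willingness to pay.
#'
#' @param components Cost ledger (default: the base-case ledger).
#' @param effects Named success probabilities per arm.
#' @param params An [econ_params()] object.
#' @return Tibble, one row per perspective: arm costs, `delta_cost_cad`,
#'   `delta_cost_usd`, `icer_reportable`, `lambda`, `inb`.
#' @export
#' @examples
#' base_case()
base_case <- function(components = default_cost_components(),
                      effects = default_effects(),
                      params = econ_params()) {
  params <- as_econ_params(params)
  breakdown <- aggregate_costs(components)
  lambda <- wtp_per_effect(params$wtp_per_qaly, params$qaly_loss_per_complication)
  purrr::map_dfr(c("societal", "health_system"), function(persp) {
    comp <- incremental(breakdown, effects, perspective = persp)
    ic <- icer(comp)
    col <- if (persp == "societal") "total" else "health_system"
    tibble::tibble(
      perspective = persp,
      cost_mobile = breakdown[[col]][breakdown$arm == "mobile"],
      cost_in_person = breakdown[[col]][breakdown$arm == "in_person"],
      delta_cost_cad = comp$delta_cost,
      delta_cost_usd = to_usd(comp$delta_cost, params$exchange_rate_usd_per_cad),
      delta_effect = comp$delta_effect,
      icer_reportable = ic$reportable,
      quadrant = ic$quadrant,
      lambda = lambda,
      inb = inb(comp, lambda)$inb
    )
  })
}
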