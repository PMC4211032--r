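#' Specification of the probabilistic sensitivity analysis
#'
#' Distribution assignments for the uncertain parameters: a uniform of
#' relative half-width `clinic_cost_rel_halfwidth` around the in-person
#' health-system (clinic) subtotal, independent uniforms of absolute
#' half-width `effect_abs_halfwidth` around each arm's success
#' probability (truncated to `[0, 1]`), and a gamma distribution for the
#' patient hourly wage parameterised by mean and coefficient of
#' variation. No mobile-arm cost parameter is varied. `wage_cv = 0` is
#' permitted and degenerates the wage to its mean, which makes an
#' all-degenerate specification reproduce the deterministic base case
#' exactly.
#'
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed; the same seed reproduces the result draw for
#'   draw.
#' @param clinic_cost_rel_halfwidth Relative half-width of the clinic
#'   cost uniform (default 0.20, i.e. +/-20%).
#' @param effect_abs_halfwidth Absolute half-width of the effect uniforms
#'   (default 0.02, i.e. +/-2 percentage points).
#' @param wage_mean Mean patient wage, CAD/h. Default $20.78/h, the mean
#'   implied by the base-case leisure cost ($102.24 over 1.64 visits of
#'   3 h).
#' @param wage_cv Coefficient of variation of the gamma wage (default
#'   0.4; >= 0, 0 meaning a point mass at the mean).
#' @return A `psa_spec` object.
#' @export
psa_spec <- function(n_draws = 10000,
                     seed = 20140922,
                     clinic_cost_rel_halfwidth = 0.20,
                     effect_abs_halfwidth = 0.02,
                     wage_mean = 102.24 / (1.64 * 3),
                     wage_cv = 0.4) {
  check_scalar_number(n_draws, "n_draws", min = 1)
  check_scalar_number(seed, "seed")
  check_scalar_number(clinic_cost_rel_halfwidth, "clinic_cost_rel_halfwidth",
                      min = 0)
  check_scalar_number(effect_abs_halfwidth, "effect_abs_halfwidth", min = 0)
  check_scalar_number(wage_mean, "wage_mean", min = 0, strict_min = TRUE)
  check_scalar_number(wage_cv, "wage_cv", min = 0)
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         clinic_cost_rel_halfwidth = clinic_cost_rel_halfwidth,
         effect_abs_halfwidth = effect_abs_halfwidth,
         wage_mean = wage_mean, wage_cv = wage_cv),
    class = "psa_spec"
  )
}

#' @export
print.psa_spec <- function(x, ...) {
  cat("<psa_spec>\n")
  cat(sprintf("  draws %d, seed %d\n", x$n_draws, x$seed))
  cat(sprintf("  clinic cost: uniform +/-%.0f%%\n",
              100 * x$clinic_cost_rel_halfwidth))
  cat(sprintf("  effects: uniform +/-%.1f pp, truncated to [0, 1]\n",
              100 * x$effect_abs_halfwidth))
  cat(sprintf("  wage: gamma(mean %.2f, cv %.2f)\n", x$wage_mean, x$wage_cv))
  invisible(x)
}

draw_gamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty through the decision
#' model. Per draw, in a fixed order for reproducibility (clinic cost,
#' mobile effect, in-person effect, wage): the in-person clinic
#' (health-system) subtotal is drawn uniformly within its relative
#' half-width; each arm's effect uniformly within its absolute
#' half-width, truncated to `[0, 1]`; and the patient wage from the gamma
#' distribution, feeding the leisure cost (wage x 3 h x 1.64 visits).
#' Caregiver, travel and parking stay at their ledger values and the
#' mobile-arm cost is held at its deterministic ledger sum throughout —
#' no mobile parameter is varied.
#'
#' @param spec A [psa_spec()].
#' @param components Cost ledger.
#' @param effects Named base success probabilities per arm.
#' @param params An [econ_params()] object.
#' @return A `cea_psa` object holding the draw table (`$draws`: societal
#'   costs, effects, and the incremental columns `delta_cost` = cost
#'   saving and `delta_effect`), the spec, the per-effect willingness to
#'   pay, and the deterministic base case. Use [tidy()] for the draws,
#'   [glance()] for summaries, [ceac()] and [icer_plane()] downstream.
#' @export
#' @examples
#' psa <- run_psa(psa_spec(n_draws = 500, seed = 1))
#' glance(psa)
run_psa <- function(spec = psa_spec(),
                    components = default_cost_components(),
                    effects = default_effects(),
                    params = econ_params()) {
  stopifnot(inherits(spec, "psa_spec"))
  params <- as_econ_params(params)
  for (e in c("mobile", "in_person")) {
    check_probability(effects[[e]], paste0("effects[", e, "]"))
  }
  pv <- per_visit_costs(components, params)
  breakdown <- aggregate_costs(components)
  cost_mobile <- breakdown$total[breakdown$arm == "mobile"]
  patient_fixed <- pv$caregiver_first_visit + pv$travel_total + pv$parking_total
  leisure_hours_total <- params$leisure_hours_per_visit * params$visits_per_month

  n <- spec$n_draws
  h <- spec$clinic_cost_rel_halfwidth
  w <- spec$effect_abs_halfwidth
  set.seed(spec$seed)
  clinic <- runif(n, pv$hs_subtotal * (1 - h), pv$hs_subtotal * (1 + h))
  e_mob <- pmin(pmax(runif(n, effects[["mobile"]] - w,
                           effects[["mobile"]] + w), 0), 1)
  e_in <- pmin(pmax(runif(n, effects[["in_person"]] - w,
                          effects[["in_person"]] + w), 0), 1)
  wage <- draw_gamma_mean_cv(n, spec$wage_mean, spec$wage_cv)

  cost_in <- clinic + wage * leisure_hours_total + patient_fixed
  draws <- tibble::tibble(
    .draw = seq_len(n),
    cost_mobile = rep(cost_mobile, n),
    cost_in_person = cost_in,
    effect_mobile = e_mob,
    effect_in_person = e_in,
    delta_cost = cost_in - cost_mobile,
    delta_effect = e_mob - e_in
  )
  base <- list(
    cost_mobile = cost_mobile,
    cost_in_person = pv$hs_subtotal + spec$wage_mean * leisure_hours_total +
      patient_fixed,
    effect_mobile = effects[["mobile"]],
    effect_in_person = effects[["in_person"]]
  )
  structure(
    list(draws = draws, spec = spec, base = base,
         lambda = wtp_per_effect(params$wtp_per_qaly,
                                 params$qaly_loss_per_complication)),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cea_psa> %d draws (seed %d)\n", x$spec$n_draws, x$spec$seed))
  cat(sprintf("  mobile cost:    mean $%.2f (sd %.2f)\n",
              g$mean_cost_mobile, g$sd_cost_mobile))
  cat(sprintf("  in-person cost: mean $%.2f (sd %.2f)\n",
              g$mean_cost_in_person, g$sd_cost_in_person))
  cat(sprintf("  preferred at lambda $%.2f: %.1f%% of draws\n",
              x$lambda, 100 * g$p_preferred))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `cea_psa` object.
#' @param ... Unused.
#' @export
tidy.cea_psa <- function(x, ...) {
  x$draws
}

#' @rdname run_psa
#' @export
glance.cea_psa <- function(x, ...) {
  d <- x$draws
  tibble::tibble(
    n_draws = nrow(d),
    mean_cost_mobile = mean(d$cost_mobile),
    sd_cost_mobile = sd(d$cost_mobile),
    mean_cost_in_person = mean(d$cost_in_person),
    sd_cost_in_person = sd(d$cost_in_person),
    mean_delta_cost = mean(d$delta_cost),
    mean_delta_effect = mean(d$delta_effect),
    p_delta_effect_negative = mean(d$delta_effect < 0),
    lambda = x$lambda,
    p_preferred = mean(x$lambda * d$delta_effect + d$delta_cost > 0)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the intervention is preferred, i.e. `lambda * delta_effect +
#' delta_cost_saving > 0`. Ties (INB exactly zero) are not counted as
#' preferred: the rule is strict inequality.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param lambda_grid Willingness-to-pay values, CAD per effect.
#' @return A `cea_ceac` tibble: `lambda`, `p_preferred` in `[0, 1]`.
#' @export
#' @examples
#' psa <- run_psa(psa_spec(n_draws = 500, seed = 1))
#' ceac(psa, lambda_grid = c(0, 4398.80, 10000))
ceac <- function(psa, lambda_grid = seq(0, 12000, by = 250)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (nrow(psa$draws) == 0) stop_validation("PSA result is empty.")
  if (any(lambda_grid < 0)) stop_validation("`lambda_grid` must be >= 0.")
  d <- psa$draws
  out <- tibble::tibble(
    lambda = lambda_grid,
    p_preferred = purrr::map_dbl(lambda_grid,
                                 ~ mean(.x * d$delta_effect + d$delta_cost > 0))
  )
  structure(out, class = c("cea_ceac", class(out)))
}

#' ICER plane of the PSA draws
#'
#' Per-draw incremental effect and incremental cost in the conventional
#' intervention-minus-comparator orientation (so the base case sits at
#' effect difference 0, cost difference about -$245: mobile cheaper),
#' with the cost-effectiveness quadrant of each draw and quadrant counts
#' as the `quadrant_counts` attribute.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @return A `cea_icer_plane` tibble: `.draw`, `delta_effect`,
#'   `delta_cost` (intervention minus comparator), `quadrant`.
#' @export
#' @examples
#' psa <- run_psa(psa_spec(n_draws = 500, seed = 1))
#' attr(icer_plane(psa), "quadrant_counts")
icer_plane <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"))
  if (nrow(psa$draws) == 0) stop_validation("PSA result is empty.")
  out <- psa$draws |>
    dplyr::transmute(
      .draw = .data$.draw,
      delta_effect = .data$delta_effect,
      delta_cost = -.data$delta_cost
    ) |>
    dplyr::mutate(quadrant = quadrant_label(.data$delta_cost,
                                            .data$delta_effect))
  counts <- out |> dplyr::count(.data$quadrant, name = "n_draws")
  structure(out, quadrant_counts = counts,
            class = c("cea_icer_plane", class(out)))
}
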