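#' Global economic constants of the follow-up model
#'
#' Bundles the economic parameters that the costing and decision functions
#' share: the willingness-to-pay threshold, the quality-of-life decrement
#' attached to a minor postoperative complication, the exchange rate used
#' for presentation, and the per-visit resource assumptions for the
#' conventional in-person arm.
#'
#' Defaults reflect the base-case calibration of the model:
#' \describe{
#'   \item{`wtp_per_qaly`}{$109,970 CAD per quality-adjusted life year
#'     (a $100,000 USD threshold expressed in CAD).}
#'   \item{`qaly_loss_per_complication`}{0.04 QALY lost to one superficial
#'     skin infection, the typical complication in this population.}
#'   \item{`exchange_rate_usd_per_cad`}{0.9102 USD per CAD, the
#'     presentation rate consistent with the base-case dollar figures.}
#'   \item{`visits_per_month`}{1.64 in-person visits attended per patient
#'     over the first postoperative month (observed clinic attendance).}
#'   \item{`clinic_hours_per_visit`}{1 h at clinic (parking, registration,
#'     and the consult).}
#'   \item{`leisure_hours_per_visit`}{3 h of foregone leisure per visit:
#'     the clinic hour plus about two hours of round-trip travel. This is a
#'     calibration: 3 h times the $11.28/h homemaker wage equals the
#'     $33.84 caregiver cost per visit.}
#'   \item{`caregiver_hourly_wage`}{$11.28/h, the Ontario homemaker wage
#'     assigned to the caregiver presumed present at the first visit.}
#'   \item{`parking_per_visit`}{$20.00 per visit ($32.80 per 1.64 visits).}
#'   \item{`travel_cost_per_km`}{Per-km driving cost, calibrated so a
#'     152 km round trip (2 x 76 km mean one-way distance) over 1.64
#'     visits costs $38.11, i.e. about $0.153/km.}
#'   \item{`amortization_years`}{5-year useful lifespan over which
#'     mobile-arm start-up costs are spread.}
#'   \item{`patients_per_year`}{1000 patients enrolled per year in the
#'     mobile arm.}
#'   \item{`data_mb_per_submission`}{0.35 MB per mobile submission
#'     (questionnaire plus photo).}
#'   \item{`data_price_per_gb`}{$22.50/GB ($45 for a 2 GB plan).}
#' }
#'
#' @param wtp_per_qaly Willingness to pay per QALY, CAD.
#' @param qaly_loss_per_complication QALY decrement per complication.
#' @param exchange_rate_usd_per_cad USD per CAD presentation rate.
#' @param visits_per_month Mean in-person visits per 30-day horizon.
#' @param clinic_hours_per_visit Hours spent at clinic per visit.
#' @param leisure_hours_per_visit Foregone leisure hours per visit
#'   (clinic time plus travel time).
#' @param caregiver_hourly_wage Caregiver wage, CAD/h.
#' @param parking_per_visit Parking cost per visit, CAD.
#' @param travel_cost_per_km Driving cost per km, CAD.
#' @param amortization_years Years over which start-up costs amortize.
#' @param patients_per_year Mobile-arm enrolment per year.
#' @param data_mb_per_submission MB of mobile data per submission.
#' @param data_price_per_gb Price of mobile data, CAD/GB.
#' @return An object of class `econ_params` (a validated named list).
#' @export
#' @examples
#' p <- econ_params()
#' wtp_per_effect(p$wtp_per_qaly, p$qaly_loss_per_complication)
econ_params <- function(wtp_per_qaly = 109970,
                        qaly_loss_per_complication = 0.04,
                        exchange_rate_usd_per_cad = 0.9102,
                        visits_per_month = 1.64,
                        clinic_hours_per_visit = 1,
                        leisure_hours_per_visit = 3,
                        caregiver_hourly_wage = 11.28,
                        parking_per_visit = 20,
                        travel_cost_per_km = 38.11 / (1.64 * 152),
                        amortization_years = 5,
                        patients_per_year = 1000,
                        data_mb_per_submission = 0.35,
                        data_price_per_gb = 45 / 2) {
  p <- list(
    wtp_per_qaly = wtp_per_qaly,
    qaly_loss_per_complication = qaly_loss_per_complication,
    exchange_rate_usd_per_cad = exchange_rate_usd_per_cad,
    visits_per_month = visits_per_month,
    clinic_hours_per_visit = clinic_hours_per_visit,
    leisure_hours_per_visit = leisure_hours_per_visit,
    caregiver_hourly_wage = caregiver_hourly_wage,
    parking_per_visit = parking_per_visit,
    travel_cost_per_km = travel_cost_per_km,
    amortization_years = amortization_years,
    patients_per_year = patients_per_year,
    data_mb_per_submission = data_mb_per_submission,
    data_price_per_gb = data_price_per_gb
  )
  for (nm in names(p)) {
    check_scalar_number(p[[nm]], nm, min = 0, strict_min = TRUE)
  }
  structure(p, class = "econ_params")
}

#' @export
print.econ_params <- function(x, ...) {
  cat("<econ_params>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_econ_params <- function(x) {
  if (inherits(x, "econ_params")) return(x)
  if (!is.list(x)) stop_validation("`params` must be an econ_params object.")
  unknown <- setdiff(names(x), names(formals(econ_params)))
  if (length(unknown) > 0) {
    stop_validation("Unknown econ_params field(s): %s",
                    paste(unknown, collapse = ", "))
  }
  do.call(econ_params, x)
}
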