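ledger_with_subtotals <- function(components) {
  components <- cost_components(components)
  breakdown <- aggregate_costs(components)
  subtotal_rows <- breakdown |>
    tidyr::pivot_longer(dplyr::all_of(c(payer_levels, "total")),
                        names_to = "payer", values_to = "amount") |>
    dplyr::mutate(
      label = ifelse(.data$payer == "total",
                     "Total societal costs",
                     paste0(.data$payer, " subtotal")),
      payer = ifelse(.data$payer == "total", "societal", .data$payer),
      kind = "subtotal",
      amount = round_half_up(.data$amount)
    )
  dplyr::bind_rows(
    dplyr::mutate(components, amount = round_half_up(.data$amount, 2)),
    subtotal_rows[c("arm", "label", "payer", "kind", "amount")]
  )
}

#' Render the model's tabular and graphical report
#'
#' Writes the base-case results and any supplied sensitivity-analysis
#' results to an output directory, with whole-dollar (half-up) rounding
#' applied here and nowhere else in the package:
#' \describe{
#'   \item{`ledger.csv`}{component rows (2 decimals) plus per-payer
#'     subtotal and societal total rows (whole dollars).}
#'   \item{`basecase.csv`}{both perspectives: arm costs, cost saving in
#'     CAD and USD (whole dollars), ICER reportability, INB.}
#'   \item{`twoway.csv`}{the INB grid at 2 decimals (if supplied).}
#'   \item{`psa_summary.csv`, `ceac.csv`, `icer_plane.csv`}{PSA summaries
#'     and curves (if a PSA result is supplied).}
#'   \item{`report.json`}{all of the above plus a provenance block
#'     (configuration hash, seeds, package version).}
#'   \item{`*.pdf`}{ICER-plane and CEAC plots (if `write_plots`).}
#' }
#' Reruns with the same configuration and seeds produce byte-identical
#' CSV files.
#'
#' @param dir Output directory (created if needed).
#' @param config A `cea_config` (default: the packaged base case).
#' @param psa Optional `cea_psa` from [run_psa()].
#' @param twoway Optional `cea_twoway` from [two_way()].
#' @param lambda_grid Willingness-to-pay grid for the CEAC.
#' @param write_plots Write PDF plots alongside the tables.
#' @return Invisibly, a list with the report tables and the provenance
#'   block.
#' @export
#' @examples
#' out <- render_report(tempfile("report"), write_plots = FALSE)
#' names(out)
render_report <- function(dir,
                          config = default_config(),
                          psa = NULL,
                          twoway = NULL,
                          lambda_grid = seq(0, 12000, by = 250),
                          write_plots = TRUE) {
  stopifnot(inherits(config, "cea_config"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      abort(sprintf("Cannot create output directory: %s", dir),
            class = "ambucea_io_error")
    }
  }
  ledger <- ledger_with_subtotals(config$components)
  readr::write_csv(ledger, file.path(dir, "ledger.csv"))

  bc <- base_case(config$components, config$effects, config$params)
  bc_out <- bc |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("cost_mobile", "cost_in_person",
                      "delta_cost_cad", "delta_cost_usd", "inb")),
      round_half_up))
  readr::write_csv(bc_out, file.path(dir, "basecase.csv"))

  report <- list(ledger = ledger, basecase = bc_out)

  if (!is.null(twoway)) {
    stopifnot(inherits(twoway, "cea_twoway"))
    tw_out <- dplyr::mutate(tibble::as_tibble(twoway),
                            inb = round_half_up(.data$inb, 2))
    readr::write_csv(tw_out, file.path(dir, "twoway.csv"))
    report$twoway <- tw_out
  }

  if (!is.null(psa)) {
    stopifnot(inherits(psa, "cea_psa"))
    psa_sum <- glance(psa)
    readr::write_csv(psa_sum, file.path(dir, "psa_summary.csv"))
    cv <- ceac(psa, lambda_grid)
    readr::write_csv(tibble::as_tibble(cv), file.path(dir, "ceac.csv"))
    plane <- icer_plane(psa)
    readr::write_csv(tibble::as_tibble(plane), file.path(dir, "icer_plane.csv"))
    report$psa_summary <- psa_sum
    report$ceac <- cv
    report$quadrant_counts <- attr(plane, "quadrant_counts")
    if (write_plots) {
      ggplot2::ggsave(file.path(dir, "icer_plane.pdf"), autoplot(plane),
                      width = 6, height = 5)
      ggplot2::ggsave(file.path(dir, "ceac.pdf"), autoplot(cv),
                      width = 6, height = 4)
    }
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    psa_seed = if (!is.null(psa)) psa$spec$seed else config$psa$seed,
    cohort_seed = config$cohort$seed,
    package_version = as.character(packageVersion("ambucea"))
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
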