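config_sections <- c("arms", "econ_params", "psa", "cohort")

#' Default run configuration
#'
#' The packaged base-case configuration as an in-memory `cea_config`: the
#' Table-style cost ledger of both arms, equal 0.96 success
#' probabilities, the global economic constants, the PSA distribution
#' assignments, and the synthetic-cohort parameters. The same
#' configuration ships as YAML at
#' `system.file("extdata", "config.yaml", package = "ambucea")`.
#'
#' @return A `cea_config` object.
#' @export
default_config <- function() {
  new_config(
    components = default_cost_components(),
    effects = default_effects(),
    params = econ_params(),
    psa = psa_spec(),
    cohort = cohort_params()
  )
}

new_config <- function(components, effects, params, psa, cohort) {
  structure(
    list(components = cost_components(components),
         effects = effects, params = params, psa = psa, cohort = cohort),
    class = "cea_config"
  )
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config>\n")
  cat(sprintf("  arms: %s (%d components)\n",
              paste(unique(x$components$arm), collapse = ", "),
              nrow(x$components)))
  cat(sprintf("  effects: %s\n",
              paste(sprintf("%s = %.2f", names(x$effects), x$effects),
                    collapse = ", ")))
  cat(sprintf("  psa: %d draws, seed %d; cohort: n = %d, seed %d\n",
              x$psa$n_draws, x$psa$seed, x$cohort$n, x$cohort$seed))
  invisible(x)
}

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop_validation("Unknown key(s) in `%s`: %s", where,
                    paste(unknown, collapse = ", "))
  }
}

parse_arms <- function(arms) {
  if (!is.list(arms) || is.null(names(arms)) || length(arms) == 0) {
    stop_validation("`arms` must be a named mapping of arm name to {p_success, components}.")
  }
  effects <- numeric(0)
  rows <- purrr::imap(arms, function(arm, nm) {
    check_known_keys(arm, c("p_success", "components"), paste0("arms$", nm))
    if (is.null(arm$p_success)) {
      stop_validation("Arm `%s` is missing `p_success`.", nm)
    }
    check_probability(arm$p_success, paste0("arms$", nm, "$p_success"))
    effects[[nm]] <<- arm$p_success
    purrr::map_dfr(arm$components, function(cmp) {
      check_known_keys(cmp, c("label", "payer", "kind", "amount"),
                       paste0("arms$", nm, "$components"))
      for (f in c("label", "payer", "kind", "amount")) {
        if (is.null(cmp[[f]])) {
          stop_validation("Component in arm `%s` is missing `%s`.", nm, f)
        }
      }
      tibble::tibble(arm = nm, label = cmp$label, payer = cmp$payer,
                     kind = cmp$kind, amount = as.numeric(cmp$amount))
    })
  })
  list(components = cost_components(dplyr::bind_rows(rows)), effects = effects)
}

build_section <- function(raw, constructor, where) {
  raw <- raw %||% list()
  check_known_keys(raw, names(formals(constructor)), where)
  do.call(constructor, raw)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `arms` (per arm: `p_success`
#' and a `components` list of `{label, payer, kind, amount}` entries),
#' `econ_params`, `psa` and `cohort`. Every field is validated with the
#' same rules as the corresponding constructor ([econ_params()],
#' [psa_spec()], [cohort_params()]); unknown keys are rejected with an
#' error naming them; fields omitted from `econ_params`, `psa` or
#' `cohort` fall back to the package defaults. An omitted `arms` section
#' falls back to the base-case ledger.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged default
#'   configuration.
#' @return A `cea_config` object.
#' @export
#' @examples
#' cfg <- load_config()
#' aggregate_costs(cfg$components)
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config.yaml", package = "ambucea")
  }
  if (!file.exists(path)) stop_validation("Config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw) || length(raw) == 0) {
    stop_validation("Empty config: required sections are %s.",
                    paste(config_sections, collapse = ", "))
  }
  check_known_keys(raw, config_sections, "config")
  if (is.null(raw$arms)) {
    components <- default_cost_components()
    effects <- default_effects()
  } else {
    parsed <- parse_arms(raw$arms)
    components <- parsed$components
    effects <- parsed$effects
  }
  new_config(
    components = components,
    effects = effects,
    params = build_section(raw$econ_params, econ_params, "econ_params"),
    psa = build_section(raw$psa, psa_spec, "psa"),
    cohort = build_section(raw$cohort, cohort_params, "cohort")
  )
}

#' Serialize a run configuration to YAML
#'
#' Inverse of [load_config()]: writing a configuration and reading it
#' back yields an identical `cea_config` (round-trip identity, up to
#' floating-point printing at 12 significant digits).
#'
#' @param config A `cea_config` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  arms <- purrr::imap(split(config$components, config$components$arm),
                      function(df, nm) {
    list(
      p_success = unname(config$effects[[nm]]),
      components = purrr::pmap(
        df[c("label", "payer", "kind", "amount")],
        function(label, payer, kind, amount) {
          list(label = label, payer = payer, kind = kind, amount = amount)
        })
    )
  })
  out <- list(
    arms = arms,
    econ_params = unclass(config$params),
    psa = unclass(config$psa),
    cohort = unclass(config$cohort)
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
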