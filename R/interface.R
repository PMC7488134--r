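#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs: the parameter source, the
#' strategy arms and starting bands, the output directory, PSA settings
#' and the engine flags.
#'
#' @param parameter_file Path to a YAML parameter file; `NULL` uses the
#'   packaged base case.
#' @param strategies Strategy arms to run.
#' @param bands Starting age bands; `NULL` means every screened band.
#' @param output_dir Directory for result files.
#' @param psa_n_iter,psa_seed,wtp_grid PSA settings.
#' @param attained_age_convention,include_baseline_cases Engine flags, see
#'   [run_cohort()].
#' @return A `run_config` list.
#' @export
run_config <- function(parameter_file = NULL,
                       strategies = c("NON_SCR", "SCR_FOL", "SCR_NFOL"),
                       bands = NULL, output_dir = tempdir(),
                       psa_n_iter = 2000, psa_seed = 20170101,
                       wtp_grid = seq(0, 102000, by = 3000),
                       attained_age_convention = "midpoint",
                       include_baseline_cases = FALSE) {
  if (length(strategies) == 0) {
    stop("at least one strategy must be requested", call. = FALSE)
  }
  bad <- setdiff(strategies, c("NON_SCR", "SCR_FOL", "SCR_NFOL"))
  if (length(bad) > 0) {
    stop("unknown strategy: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!attained_age_convention %in% c("midpoint", "lower")) {
    stop("attained_age_convention must be 'midpoint' or 'lower'",
         call. = FALSE)
  }
  structure(list(parameter_file = parameter_file, strategies = strategies,
                 bands = bands, output_dir = output_dir,
                 psa_n_iter = psa_n_iter, psa_seed = psa_seed,
                 wtp_grid = wtp_grid,
                 attained_age_convention = attained_age_convention,
                 include_baseline_cases = include_baseline_cases),
            class = "run_config")
}

config_params <- function(config) {
  if (is.null(config$parameter_file)) {
    base_case_fixture()
  } else {
    load_parameters(config$parameter_file)
  }
}

write_sidecar <- function(config, path, extra = list()) {
  meta <- c(list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("ecscreen")),
    parameter_file = config$parameter_file %||% "packaged base case",
    strategies = config$strategies,
    attained_age_convention = config$attained_age_convention,
    include_baseline_cases = config$include_baseline_cases
  ), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the base-case analysis and write result tables
#'
#' Runs every requested strategy for every starting band, and writes two
#' comma-delimited tables to the output directory:
#' `epidemiology.csv` (cumulative cancer incidence and mortality per
#' 100,000 with percent reductions versus no screening and versus
#' screening without follow-up) and `cost_effectiveness.csv` (discounted
#' costs, QALYs, dominance labels and comparison ICERs), plus a JSON
#' metadata sidecar recording the engine flags.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the two tibbles (`epidemiology`,
#'   `cost_effectiveness`) and the file paths.
#' @export
run_base_case <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- config_params(config)
  bands <- config$bands %||% start_bands(params)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  per_band <- purrr::map(bands, function(b) {
    runs <- purrr::map(config$strategies, function(s) {
      tr <- run_cohort(params, s, b,
                       attained_age_convention = config$attained_age_convention,
                       include_baseline_cases = config$include_baseline_cases)
      list(strategy = s,
           ci = cumulative_ec_incidence(tr),
           cm = cumulative_ec_mortality(tr),
           econ = accumulate_outcomes(tr, params))
    })
    names(runs) <- config$strategies

    epi <- purrr::map_dfr(runs, function(r) {
      tibble(band = b, strategy = r$strategy,
             cum_incidence = r$ci, cum_mortality = r$cm)
    })
    if ("NON_SCR" %in% names(runs)) {
      ref <- runs$NON_SCR
      epi$rci_vs_nonscr <- ifelse(
        epi$strategy == "NON_SCR", NA_real_,
        reduction_vs(epi$cum_incidence, ref$ci))
      epi$rcm_vs_nonscr <- ifelse(
        epi$strategy == "NON_SCR", NA_real_,
        reduction_vs(epi$cum_mortality, ref$cm))
    }
    if (all(c("SCR_FOL", "SCR_NFOL") %in% names(runs))) {
      epi$rci_fol_vs_nfol <- ifelse(
        epi$strategy == "SCR_FOL",
        reduction_vs(runs$SCR_FOL$ci, runs$SCR_NFOL$ci), NA_real_)
      epi$rcm_fol_vs_nfol <- ifelse(
        epi$strategy == "SCR_FOL",
        reduction_vs(runs$SCR_FOL$cm, runs$SCR_NFOL$cm), NA_real_)
    }

    outcomes <- purrr::map_dfr(runs, function(r) glance(r$econ))
    ce <- tibble(band = b, strategy = outcomes$strategy,
                 cost = outcomes$total_cost, qalys = outcomes$total_qalys)
    if (nrow(ce) >= 2) {
      dom <- dominance_analysis(
        tibble(strategy = ce$strategy, cost = ce$cost, qalys = ce$qalys))
      ce <- dplyr::left_join(ce,
                             dplyr::select(as_tibble(dom), "strategy",
                                           "label", "icer"),
                             by = "strategy")
    }
    if (all(c("SCR_FOL", "NON_SCR") %in% names(runs))) {
      ce$icer_fol_vs_nonscr <- ifelse(
        ce$strategy == "SCR_FOL",
        icer(runs$SCR_FOL$econ, runs$NON_SCR$econ), NA_real_)
    }
    if (all(c("SCR_FOL", "SCR_NFOL") %in% names(runs))) {
      ce$icer_fol_vs_nfol <- ifelse(
        ce$strategy == "SCR_FOL",
        icer(runs$SCR_FOL$econ, runs$SCR_NFOL$econ), NA_real_)
    }
    list(epi = epi, ce = ce)
  })

  epidemiology <- purrr::map_dfr(per_band, "epi")
  cost_effectiveness <- purrr::map_dfr(per_band, "ce")

  epi_path <- file.path(config$output_dir, "epidemiology.csv")
  ce_path <- file.path(config$output_dir, "cost_effectiveness.csv")
  utils::write.csv(epidemiology, epi_path, row.names = FALSE)
  utils::write.csv(cost_effectiveness, ce_path, row.names = FALSE)
  meta_path <- file.path(config$output_dir, "run_metadata.json")
  write_sidecar(config, meta_path, list(bands = bands, stage = "base_case"))

  message("base case: ", length(bands), " band(s) x ",
          length(config$strategies), " strategies -> ", config$output_dir)
  invisible(list(epidemiology = epidemiology,
                 cost_effectiveness = cost_effectiveness,
                 files = c(epi_path, ce_path, meta_path)))
}

#' Run the sensitivity analyses and write result tables
#'
#' Runs the PSA for one band and writes `ceac.csv` (strategy x WTP grid),
#' `ce_plane.csv` (per-iteration incremental cost/QALY points versus no
#' screening) with the fitted confidence-ellipse parameters in the JSON
#' sidecar, and `tornado.csv` (one-way results sorted by span).
#'
#' @param config A [run_config()].
#' @param band Starting age band for the PSA and tornado.
#' @param tornado Logical; run the one-way analysis too (default `TRUE`).
#' @return Invisibly, a list with `psa`, `ceac`, `plane`, `tornado` and
#'   file paths.
#' @export
run_sensitivity <- function(config = run_config(), band = "40-44",
                            tornado = TRUE) {
  stopifnot(inherits(config, "run_config"))
  params <- config_params(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  psa <- run_psa(params, n_iter = config$psa_n_iter, seed = config$psa_seed,
                 band = band, strategies = config$strategies)
  cc <- ceac(psa, config$wtp_grid)
  ceac_path <- file.path(config$output_dir, "ceac.csv")
  utils::write.csv(cc, ceac_path, row.names = FALSE)

  plane <- NULL
  plane_path <- NULL
  if (all(c("SCR_FOL", "NON_SCR") %in% config$strategies)) {
    plane <- ce_plane_ellipse(psa, "SCR_FOL", "NON_SCR")
    plane_path <- file.path(config$output_dir, "ce_plane.csv")
    utils::write.csv(plane$points, plane_path, row.names = FALSE)
  }

  tor <- NULL
  tor_path <- NULL
  if (tornado) {
    tor <- one_way_sa(params, band = band)
    tor_path <- file.path(config$output_dir, "tornado.csv")
    utils::write.csv(tor, tor_path, row.names = FALSE)
  }

  meta_path <- file.path(config$output_dir, "sensitivity_metadata.json")
  write_sidecar(config, meta_path, list(
    stage = "sensitivity", band = band,
    psa_n_iter = psa$n_iter, psa_seed = psa$seed,
    psa_failed_draws = psa$failed,
    ellipse = if (!is.null(plane)) list(
      center = as.list(plane$center),
      cov = as.numeric(plane$cov), level = plane$level,
      degenerate = plane$degenerate)))

  message("sensitivity: PSA n=", psa$n_iter, " band ", band, " -> ",
          config$output_dir)
  invisible(list(psa = psa, ceac = cc, plane = plane, tornado = tor,
                 files = c(ceac_path, plane_path, tor_path, meta_path)))
}

#' Check a parameter file without running anything
#'
#' @param path Path to a YAML parameter file.
#' @return `TRUE` invisibly if the file validates; otherwise the loader's
#'   error is re-thrown.
#' @export
validate_parameter_file <- function(path) {
  load_parameters(path)
  message("OK: ", path)
  invisible(TRUE)
}
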