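#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

PARAM_SCHEMA_VERSION <- 1L

state_named <- function(x, what) {
  if (!all(health_states() %in% names(x))) {
    stop("`", what, "` must name every health state; missing: ",
         paste(setdiff(health_states(), names(x)), collapse = ", "),
         call. = FALSE)
  }
  unlist(x)[health_states()]
}

parse_band <- function(band) {
  m <- regmatches(band, regexec("^([0-9]+)-([0-9]+)$", band))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed age band label(s): ", paste(band[bad], collapse = ", "),
         call. = FALSE)
  }
  lower <- vapply(m, function(z) as.numeric(z[2]), 1)
  upper <- vapply(m, function(z) as.numeric(z[3]), 1)
  tibble(band = band, lower = lower, upper = upper)
}

#' Load a model parameter file
#'
#' Reads a structured-text (YAML) parameter file following the documented
#' schema (`schema_version: 1`), checks every field against the model's
#' invariants and returns a validated parameter set.  Rates are kept on
#' their printed per-100,000-per-year scale; conversion to per-person
#' probabilities happens inside the calibration functions.
#'
#' @param path Path to a YAML parameter file.
#' @return An object of class `ecscreen_params`: a named list with elements
#'   `econ`, `age_rates` (a tibble), `stage`, `costs`, `utilities`
#'   (a tibble) and `scalars`.
#' @seealso [base_case_fixture()], [write_parameters()],
#'   [validate_parameters()]
#' @export
#' @examples
#' p <- base_case_fixture()
#' p$age_rates
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)

  allowed <- c("schema_version", "currency", "rate_scale", "economics",
               "age_rates", "stage_distribution", "costs", "utilities",
               "scalars")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown top-level key(s) in parameter file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c("schema_version", "economics", "age_rates",
                       "stage_distribution", "costs", "utilities", "scalars"),
                     names(raw))
  if (length(missing) > 0) {
    stop("parameter file is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.integer(raw$schema_version), PARAM_SCHEMA_VERSION)) {
    stop("unsupported schema_version: ", raw$schema_version, call. = FALSE)
  }

  econ_keys <- c("discount_rate", "inflation_rate", "wtp", "cohort_size",
                 "cycle_length", "horizon_age")
  if (!setequal(names(raw$economics), econ_keys)) {
    stop("economics block must contain exactly: ",
         paste(econ_keys, collapse = ", "), call. = FALSE)
  }
  econ <- lapply(raw$economics, as.numeric)

  rate_keys <- c("band", "ec_incidence", "ec_incidence_lgin", "ec_detection",
                 "lgin_detection", "ec_mortality", "all_cause_mortality")
  rows <- purrr::map(raw$age_rates, function(r) {
    unknown <- setdiff(names(r), rate_keys)
    if (length(unknown) > 0) {
      stop("unknown age-rate field(s) in band ", r$band %||% "?", ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    need <- setdiff(rate_keys, c("ec_detection", "lgin_detection"))
    miss <- setdiff(need, names(r))
    if (length(miss) > 0) {
      stop("age-rate band ", r$band %||% "?", " is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tibble(
      band = r$band,
      ec_incidence = as.numeric(r$ec_incidence),
      ec_incidence_lgin = as.numeric(r$ec_incidence_lgin),
      ec_detection = as.numeric(r$ec_detection %||% NA_real_),
      lgin_detection = as.numeric(r$lgin_detection %||% NA_real_),
      ec_mortality = as.numeric(r$ec_mortality),
      all_cause_mortality = as.numeric(r$all_cause_mortality)
    )
  })
  age_rates <- dplyr::bind_rows(rows)
  age_rates <- dplyr::bind_cols(
    parse_band(age_rates$band),
    dplyr::select(age_rates, -"band")
  )

  sd_raw <- raw$stage_distribution
  stage <- list(
    nonscreening = unlist(sd_raw$nonscreening)[c("ic", "sm", "mod", "adv")],
    screening = unlist(sd_raw$screening)[c("ic", "sm", "mod", "adv")],
    sa_range = sd_raw$sa_range,
    distribution = sd_raw$distribution %||% "dirichlet"
  )

  costs <- list(
    screening = state_named(raw$costs$screening, "costs$screening"),
    treatment = state_named(raw$costs$treatment, "costs$treatment"),
    sa_fraction = as.numeric(raw$costs$sa_fraction %||% 0.30),
    distribution = raw$costs$distribution %||% "gamma"
  )

  util_raw <- raw$utilities
  util_states <- setdiff(names(util_raw), "distribution")
  utilities <- purrr::map_dfr(util_states, function(s) {
    u <- util_raw[[s]]
    tibble(state = s, mean = as.numeric(u$mean), sd = as.numeric(u$sd),
           sa_lo = as.numeric(u$sa_range[[1]]),
           sa_hi = as.numeric(u$sa_range[[2]]))
  })

  params <- structure(
    list(
      schema_version = PARAM_SCHEMA_VERSION,
      currency = raw$currency %||% "USD-2017",
      rate_scale = as.numeric(raw$rate_scale %||% 1e5),
      econ = econ,
      age_rates = age_rates,
      stage = stage,
      costs = costs,
      utilities = utilities,
      scalars = raw$scalars
    ),
    class = "ecscreen_params"
  )
  validate_parameters(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

renormalize_simplex <- function(p, what, tol = 1e-6) {
  if (any(p < 0 | p > 1)) {
    stop(what, ": proportions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(what, ": proportions sum to ", format(s),
         ", outside tolerance ", tol, call. = FALSE)
  }
  if (s != 1) {
    if (abs(s - 1) > 1e-9) {
      warning(what, ": renormalizing proportions (sum = ", format(s), ")",
              call. = FALSE)
    }
    p <- p / s
  }
  p
}

scalar_value <- function(scalars, key) {
  v <- scalars[[key]]$value
  if (is.null(v)) stop("scalar `", key, "` missing from parameter set",
                       call. = FALSE)
  as.numeric(v)
}

#' Validate a model parameter set
#'
#' Checks every invariant of the parameter schema: age bands contiguous and
#' covering ages 40--79, non-negative rates with all-cause mortality at
#' least the cancer-specific mortality in every band, stage distributions
#' on the probability simplex (renormalized with a warning when off by at
#' most 1e-6), non-negative costs with zero cost in `DEATH` and zero
#' treatment cost in `NORMAL`, utilities in `[0, 1]` anchored at 1 for
#' `NORMAL` and 0 for `DEATH`, transition scalars in `[0, 1]` with simplex
#' progression splits, and elderly death-risk multipliers at least 1.
#'
#' @param params An `ecscreen_params` object.
#' @return The validated (possibly renormalized) object, invisibly usable
#'   in a pipe.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ecscreen_params"))
  e <- params$econ
  if (e$discount_rate < 0 || e$discount_rate >= 1) {
    stop("discount_rate must lie in [0, 1)", call. = FALSE)
  }
  if (e$inflation_rate < 0 || e$inflation_rate >= 1) {
    stop("inflation_rate must lie in [0, 1)", call. = FALSE)
  }
  if (e$cohort_size <= 0) stop("cohort_size must be positive", call. = FALSE)
  if (e$cycle_length != 1) {
    stop("only a 1-year cycle length is supported", call. = FALSE)
  }

  ar <- params$age_rates
  if (nrow(ar) < 1) stop("age_rates is empty", call. = FALSE)
  ord <- order(ar$lower)
  ar <- ar[ord, ]
  if (any(ar$upper < ar$lower)) {
    stop("age band upper bound below lower bound", call. = FALSE)
  }
  if (nrow(ar) > 1 && any(ar$lower[-1] != ar$upper[-nrow(ar)] + 1)) {
    stop("age bands must be contiguous and non-overlapping", call. = FALSE)
  }
  if (ar$upper[nrow(ar)] < e$horizon_age) {
    stop("age bands must cover ages up to the horizon (",
         e$horizon_age, ")", call. = FALSE)
  }
  num_cols <- c("ec_incidence", "ec_incidence_lgin", "ec_detection",
                "lgin_detection", "ec_mortality", "all_cause_mortality")
  for (cc in num_cols) {
    v <- ar[[cc]]
    if (any(!is.na(v) & v < 0)) {
      stop("age_rates$", cc, " contains negative values", call. = FALSE)
    }
  }
  bad <- ar$all_cause_mortality < ar$ec_mortality
  if (any(bad)) {
    stop("all-cause mortality below EC mortality in band(s): ",
         paste(ar$band[bad], collapse = ", "),
         " (background death probability would be negative)", call. = FALSE)
  }
  params$age_rates <- ar

  params$stage$nonscreening <- renormalize_simplex(
    params$stage$nonscreening, "stage_distribution$nonscreening")
  params$stage$screening <- renormalize_simplex(
    params$stage$screening, "stage_distribution$screening")

  for (side in c("screening", "treatment")) {
    cv <- params$costs[[side]]
    if (any(cv < 0)) stop("costs$", side, " contains negative values",
                          call. = FALSE)
    if (cv[["DEATH"]] != 0) stop("DEATH must carry zero cost", call. = FALSE)
  }
  if (params$costs$treatment[["NORMAL"]] != 0) {
    stop("NORMAL must carry zero treatment cost", call. = FALSE)
  }

  ut <- params$utilities
  if (!setequal(ut$state, health_states())) {
    stop("utilities must cover exactly the 11 health states", call. = FALSE)
  }
  if (any(ut$mean < 0 | ut$mean > 1)) {
    stop("utility means must lie in [0, 1]", call. = FALSE)
  }
  if (any(ut$sd < 0)) stop("utility SDs must be non-negative", call. = FALSE)
  u_norm <- ut[ut$state == "NORMAL", ]
  u_death <- ut[ut$state == "DEATH", ]
  if (u_norm$mean != 1 || u_norm$sd != 0) {
    stop("NORMAL utility must be exactly 1 with SD 0", call. = FALSE)
  }
  if (u_death$mean != 0 || u_death$sd != 0) {
    stop("DEATH utility must be exactly 0 with SD 0", call. = FALSE)
  }

  sc <- params$scalars
  prob_keys <- c("lgin_to_normal", "ic_to_dfs_gross", "ic_progress",
                 "dfs_ic_to_ic", "dfs_ic_progress", "sm_to_dfs_gross",
                 "sm_progress", "dfs_sm_to_sm", "dfs_sm_progress",
                 "mod_to_dfs_gross", "mod_to_adv", "dfs_mod_to_mod",
                 "dfs_mod_to_adv", "adv_to_pfs_gross", "pfs_progress")
  for (k in prob_keys) {
    v <- scalar_value(sc, k)
    if (v < 0 || v > 1) {
      stop("transition scalar `", k, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (scalar_value(sc, "rr_screening") <= 0) {
    stop("rr_screening must be positive", call. = FALSE)
  }
  if (scalar_value(sc, "lgin_ec_risk_ratio") <= 0) {
    stop("lgin_ec_risk_ratio must be positive", call. = FALSE)
  }
  for (split in c("ic_progress_split", "dfs_ic_progress_split",
                  "sm_progress_split")) {
    comp <- sc[[split]]
    vals <- vapply(setdiff(names(comp), "dist"),
                   function(k) as.numeric(comp[[k]]$value), 1)
    if (any(vals < 0 | vals > 1)) {
      stop("components of `", split, "` must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(vals) - 1) > 1e-6) {
      stop("components of `", split, "` must form a simplex (sum = ",
           format(sum(vals)), ")", call. = FALSE)
    }
  }
  for (k in names(sc$ec_death)) {
    v <- as.numeric(sc$ec_death[[k]]$value)
    if (v < 0 || v > 1) {
      stop("ec_death$", k, " must lie in [0, 1]", call. = FALSE)
    }
  }
  for (k in names(sc$elderly_death_rr)) {
    v <- as.numeric(sc$elderly_death_rr[[k]]$value)
    if (v < 1) {
      stop("elderly death-risk multiplier `", k, "` must be >= 1",
           call. = FALSE)
    }
  }
  params
}

#' The published base-case parameter set
#'
#' Returns the packaged base case: age-specific incidence, detection and
#' mortality schedules, stage distributions under screening and passive
#' diagnosis, state costs and utilities, all transition scalars and the
#' economic settings (5% discount, 4.7% cost inflation, USD 51,000
#' willingness-to-pay, 100,000-person cohorts, 1-year cycles to age 79).
#'
#' @return An `ecscreen_params` object.
#' @export
#' @examples
#' p <- base_case_fixture()
#' p$costs$treatment[["MOD"]]
base_case_fixture <- function() {
  path <- system.file("extdata", "base_case.yaml", package = "ecscreen",
                      mustWork = TRUE)
  load_parameters(path)
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameters()]: the written file round-trips losslessly
#' through the loader.
#'
#' @param params An `ecscreen_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ecscreen_params"))
  ar <- params$age_rates
  age_rates <- purrr::pmap(ar, function(band, lower, upper, ec_incidence,
                                        ec_incidence_lgin, ec_detection,
                                        lgin_detection, ec_mortality,
                                        all_cause_mortality) {
    r <- list(band = band,
              ec_incidence = ec_incidence,
              ec_incidence_lgin = ec_incidence_lgin,
              ec_detection = ec_detection,
              lgin_detection = lgin_detection,
              ec_mortality = ec_mortality,
              all_cause_mortality = all_cause_mortality)
    r[!vapply(r, function(x) is.numeric(x) && is.na(x), TRUE)]
  })
  ut <- params$utilities
  utilities <- stats::setNames(
    purrr::pmap(ut, function(state, mean, sd, sa_lo, sa_hi) {
      list(mean = mean, sd = sd, sa_range = c(sa_lo, sa_hi))
    }),
    ut$state
  )
  out <- list(
    schema_version = params$schema_version,
    currency = params$currency,
    rate_scale = params$rate_scale,
    economics = params$econ,
    age_rates = age_rates,
    stage_distribution = list(
      nonscreening = as.list(params$stage$nonscreening),
      screening = as.list(params$stage$screening),
      sa_range = params$stage$sa_range,
      distribution = params$stage$distribution
    ),
    costs = list(
      screening = as.list(params$costs$screening),
      treatment = as.list(params$costs$treatment),
      sa_fraction = params$costs$sa_fraction,
      distribution = params$costs$distribution
    ),
    utilities = c(utilities, list(distribution = "beta")),
    scalars = params$scalars
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.ecscreen_params <- function(x, ...) {
  cat("<ecscreen_params> schema v", x$schema_version, ", ", x$currency,
      "\n", sep = "")
  cat("  bands: ", paste(x$age_rates$band, collapse = " "), "\n", sep = "")
  cat("  discount ", x$econ$discount_rate, ", inflation ",
      x$econ$inflation_rate, ", WTP ", x$econ$wtp, ", cohort ",
      x$econ$cohort_size, ", horizon age ", x$econ$horizon_age, "\n",
      sep = "")
  invisible(x)
}

# Band row containing an attained age.
band_for_age <- function(params, age) {
  ar <- params$age_rates
  i <- which(age >= ar$lower & age <= ar$upper)
  if (length(i) != 1L) {
    stop("no age band covers attained age ", age, call. = FALSE)
  }
  ar[i, ]
}

# Start bands eligible for screening (those with detection rates).
start_bands <- function(params) {
  ar <- params$age_rates
  ar$band[!is.na(ar$ec_detection) & !is.na(ar$lgin_detection)]
}

stage_vec <- function(params, scenario = c("nonscreening", "screening")) {
  scenario <- match.arg(scenario)
  params$stage[[scenario]]
}
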