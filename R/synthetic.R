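#' Configuration for synthetic parameter sets
#'
#' Describes a synthetic study population with controlled ground truth so
#' every pipeline stage can be exercised on inputs other than the packaged
#' base case.  Incidence follows an exponential age trend
#' `I(age) = i40 * exp(slope * (age - 40))` per 100,000, discretized to
#' 5-year bands at their midpoints; all-cause mortality follows its own
#' exponential trend on top of the cancer-specific mortality; screening
#' shifts the stage distribution toward early stages by mixing the
#' passive-diagnosis simplex with an early-heavy simplex at weight
#' `stage_shift`.
#'
#' @param seed Integer seed controlling the jittered cost and utility
#'   draws.
#' @param i40 Annual cancer incidence per 100,000 at age 40.
#' @param incidence_slope Exponential age slope of incidence (per year).
#' @param rr Screening incidence risk ratio (annual probability scale).
#' @param stage_shift Mixing weight in `[0, 1]` toward early-stage
#'   detection under screening (0 = no shift).
#' @param lgin_prevalence_scale Scale applied to the LGIN detection
#'   schedule (0 removes LGIN from screening).
#' @param detection_multiplier Screening detection rate as a multiple of
#'   annual incidence (detected prevalence pool).
#' @param mort40 All-cause mortality per 100,000 at age 40 (background
#'   component).
#' @param mortality_slope Exponential age slope of background mortality.
#' @param cost_jitter,utility_jitter Relative half-widths of the uniform
#'   jitter applied to the base-case cost and utility profiles.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' generate_parameters(synthetic_config(seed = 1))
synthetic_config <- function(seed = 1L, i40 = 2, incidence_slope = 0.10,
                             rr = 0.70, stage_shift = 0.9,
                             lgin_prevalence_scale = 1,
                             detection_multiplier = 12,
                             mort40 = 150, mortality_slope = 0.09,
                             cost_jitter = 0.1, utility_jitter = 0.05) {
  stopifnot(i40 >= 0, rr > 0, stage_shift >= 0, stage_shift <= 1,
            lgin_prevalence_scale >= 0, detection_multiplier >= 0,
            mort40 > 0, cost_jitter >= 0, utility_jitter >= 0)
  structure(list(seed = as.integer(seed), i40 = i40,
                 incidence_slope = incidence_slope, rr = rr,
                 stage_shift = stage_shift,
                 lgin_prevalence_scale = lgin_prevalence_scale,
                 detection_multiplier = detection_multiplier,
                 mort40 = mort40, mortality_slope = mortality_slope,
                 cost_jitter = cost_jitter,
                 utility_jitter = utility_jitter),
            class = "synthetic_config")
}

#' Generate a synthetic, validated parameter set
#'
#' Builds a complete `ecscreen_params` object from a [synthetic_config()].
#' The generating values (the ground truth a test should recover) are
#' attached as attribute `ground_truth`, so tests never re-derive them.
#' A null-effect configuration (`rr = 1`, `stage_shift = 0`,
#' `lgin_prevalence_scale = 0`, `detection_multiplier` equal to incidence)
#' makes the screening-without-follow-up arm coincide exactly with no
#' screening.
#'
#' @param config A `synthetic_config`.
#' @return A validated `ecscreen_params` object.
#' @export
generate_parameters <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  base <- base_case_fixture()
  set.seed(config$seed)

  lowers <- seq(40, 75, by = 5)
  mids <- lowers + 2
  inc <- config$i40 * exp(config$incidence_slope * (mids - 40))
  ec_mort <- 0.6 * inc  # most synthetic cases are eventually fatal
  all_mort <- config$mort40 * exp(config$mortality_slope * (mids - 40)) +
    ec_mort
  if (any(all_mort < ec_mort)) {
    stop("synthetic config yields all-cause mortality below EC mortality",
         call. = FALSE)
  }
  if (any(all_mort > 1e5)) {
    stop("synthetic mortality schedule exceeds the rate scale", call. = FALSE)
  }
  screened <- mids <= 67
  detection <- ifelse(screened, config$detection_multiplier * inc, NA_real_)
  lgin_det <- ifelse(screened,
                     config$lgin_prevalence_scale * 10 * detection,
                     NA_real_)
  ar <- tibble(
    band = sprintf("%d-%d", lowers, lowers + 4),
    lower = lowers, upper = lowers + 4,
    ec_incidence = inc,
    ec_incidence_lgin = inc * scalar_value(base$scalars,
                                           "lgin_ec_risk_ratio"),
    ec_detection = detection,
    lgin_detection = lgin_det,
    ec_mortality = ec_mort,
    all_cause_mortality = all_mort
  )

  params <- base
  params$age_rates <- ar
  params$scalars$rr_screening$value <- config$rr

  early <- c(ic = 0.90, sm = 0.04, mod = 0.04, adv = 0.02)
  nonscr <- base$stage$nonscreening
  params$stage$screening <-
    (1 - config$stage_shift) * nonscr + config$stage_shift * early

  jit <- function(x, w) x * stats::runif(length(x), 1 - w, 1 + w)
  tr <- params$costs$treatment
  nz <- names(tr)[tr > 0]
  params$costs$treatment[nz] <- jit(tr[nz], config$cost_jitter)
  ut <- params$utilities
  mid_states <- !(ut$state %in% c("NORMAL", "DEATH"))
  ut$mean[mid_states] <- pmin(jit(ut$mean[mid_states],
                                  config$utility_jitter), 1)
  params$utilities <- ut

  params <- validate_parameters(params)
  attr(params, "ground_truth") <- config
  params
}

#' Cumulative incidence pair consistent with a configured risk ratio
#'
#' Constructs t-year cumulative incidences for a screened and a control
#' population whose one-year probability ratio equals the configured `rr`
#' exactly under the constant-rate model, for calibration round-trip
#' tests: [annual_prob_ratio()] applied to the pair recovers `rr`.
#'
#' @param config A [synthetic_config()]; `rr` and `i40` set the effect and
#'   the control incidence level.
#' @param t Follow-up span in years.
#' @return Named numeric vector `c(screened = ..., control = ...)` of
#'   cumulative probabilities.
#' @export
#' @examples
#' pair <- generate_cumulative_incidence_pair(synthetic_config(rr = 0.7), 10)
#' annual_prob_ratio(pair[["screened"]], pair[["control"]], 10)
generate_cumulative_incidence_pair <- function(config, t) {
  stopifnot(inherits(config, "synthetic_config"), t > 0)
  r_control <- config$i40 / 1e5
  p1_control <- rate_to_prob(r_control, 1)
  p1_screen <- p1_control * config$rr
  stopifnot(p1_screen < 1)
  cum_control <- rate_to_prob(r_control, t)
  cum_screen <- rate_to_prob(prob_to_rate(p1_screen, 1), t)
  c(screened = cum_screen, control = cum_control)
}
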