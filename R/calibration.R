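#' Convert between cumulative probabilities and annual rates
#'
#' Transition inputs published as t-year cumulative probabilities are
#' converted to constant annual rates with `r = -log(1 - p) / t`, and rates
#' back to cycle probabilities with `p = 1 - exp(-r * t)`.  The two
#' functions are mutual inverses.
#'
#' @param p Cumulative probability over `t` years, in `[0, 1)`.
#' @param r Event rate per year, `>= 0`.
#' @param t Time span in years, `> 0`.
#' @return `prob_to_rate()`: a rate per year; `rate_to_prob()`: a
#'   probability in `[0, 1)`.
#' @export
#' @examples
#' r <- prob_to_rate(0.0592, 10)
#' rate_to_prob(r, 1)
prob_to_rate <- function(p, t) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  if (any(p < 0 | p >= 1)) {
    stop("`p` must lie in [0, 1); a certain event has no finite rate",
         call. = FALSE)
  }
  -log1p(-p) / t
}

#' @rdname prob_to_rate
#' @export
rate_to_prob <- function(r, t) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  -expm1(-r * t)
}

#' Annual incidence probability ratio from cumulative incidences
#'
#' Converts two t-year cumulative incidences (screened and control) to
#' one-year probabilities via the rate transform and returns their ratio.
#' With the published 10-year cumulative ESCC incidences of 4.17%
#' (screened) and 5.92% (unscreened) this yields the screening risk ratio
#' of 0.70 used to deflate the incidence hazard in the screened arms.
#'
#' @param cum_screen,cum_control Cumulative probabilities over `t` years,
#'   both in `(0, 1)`.
#' @param t Follow-up span in years.
#' @return Dimensionless ratio of one-year probabilities.
#' @export
#' @examples
#' annual_prob_ratio(0.0417, 0.0592, 10)
annual_prob_ratio <- function(cum_screen, cum_control, t) {
  if (any(cum_control <= 0)) {
    stop("control cumulative incidence must be positive", call. = FALSE)
  }
  if (any(cum_screen <= 0)) {
    stop("screened cumulative incidence must be positive", call. = FALSE)
  }
  p1_screen <- rate_to_prob(prob_to_rate(cum_screen, t), 1)
  p1_control <- rate_to_prob(prob_to_rate(cum_control, t), 1)
  p1_screen / p1_control
}

#' Screening-adjusted annual incidence
#'
#' Deflates a published annual incidence by the screening risk ratio:
#' adjusted incidence = incidence x RR.  Applied only to the
#' normal-to-cancer hazard in the screened arms.
#'
#' @param i_p Annual incidence per 100,000.
#' @param rr Risk ratio (> 0).
#' @return Adjusted annual incidence per 100,000.
#' @export
adjusted_incidence <- function(i_p, rr) {
  if (any(i_p < 0)) stop("incidence must be non-negative", call. = FALSE)
  if (any(rr <= 0)) stop("risk ratio must be positive", call. = FALSE)
  i_p * rr
}

#' Cancer incidence among LGIN patients
#'
#' Scales the general-population annual incidence by the published risk
#' ratio of cancer incidence among LGIN patients versus healthy subjects
#' (3.66 in the base case).  The packaged base case carries a printed
#' LGIN-specific incidence column which takes precedence over this product
#' inside the engine; the function exists for synthetic parameter sets.
#'
#' @param i_p Annual incidence per 100,000 in the general population.
#' @param risk_ratio LGIN-vs-healthy incidence risk ratio.
#' @return Annual incidence per 100,000 among LGIN patients.
#' @export
lgin_ec_incidence <- function(i_p, risk_ratio) {
  if (any(i_p < 0)) stop("incidence must be non-negative", call. = FALSE)
  i_p * risk_ratio
}

#' Background (non-cancer) annual death probability
#'
#' The annual death probability for individuals without invasive cancer,
#' `d_nor`, is the difference between all-cause and cancer-specific
#' mortality for the age band, divided by the rate scale.
#'
#' @param band One row of the `age_rates` tibble (or any list with
#'   `all_cause_mortality` and `ec_mortality` per 100,000).
#' @param rate_scale Denominator of the printed rates (default 100,000).
#' @return Annual probability in `[0, 1]`.
#' @export
background_death_prob <- function(band, rate_scale = 1e5) {
  diff <- band$all_cause_mortality - band$ec_mortality
  if (any(diff < 0)) {
    stop("all-cause mortality below EC mortality", call. = FALSE)
  }
  diff / rate_scale
}

#' Cancer-specific annual death probability
#'
#' State-specific death probabilities apply to the submucosal, moderate and
#' advanced cancer states and their post-treatment survivor states.  Above
#' attained age 65 the base probability is multiplied by a stage-class risk
#' ratio (1.30 for SM, 1.20 for moderate, 1.16 for advanced classes) and
#' capped at 1.  LGIN, IC and DFS_IC carry background mortality only.
#'
#' @param state One of `SM`, `DFS_SM`, `MOD`, `DFS_MOD`, `ADV`, `PFS_ADV`.
#' @param attained_age Age in years.
#' @param scalars The `scalars` element of an `ecscreen_params` object.
#' @return Annual probability in `[0, 1]`.
#' @export
#' @examples
#' p <- base_case_fixture()
#' ec_death_prob("MOD", 70, p$scalars)
ec_death_prob <- function(state, attained_age, scalars) {
  assert_state(state)
  if (!state %in% ec_death_states()) {
    stop("`", state, "` carries background mortality only; ",
         "EC death probabilities exist for ",
         paste(ec_death_states(), collapse = ", "), call. = FALSE)
  }
  key <- c(SM = "sm", DFS_SM = "dfs_sm", MOD = "mod", DFS_MOD = "dfs_mod",
           ADV = "adv", PFS_ADV = "pfs")[[state]]
  base <- as.numeric(scalars$ec_death[[key]]$value)
  if (attained_age > 65) {
    class_key <- c(SM = "sm", DFS_SM = "sm", MOD = "mod", DFS_MOD = "mod",
                   ADV = "adv", PFS_ADV = "adv")[[state]]
    base <- base * as.numeric(scalars$elderly_death_rr[[class_key]]$value)
  }
  min(base, 1)
}

#' Initial state occupancy for a strategy and starting age band
#'
#' The starting distribution of a cohort.  In the unscreened arm the
#' cancer states receive the annual incidence times the passive-diagnosis
#' stage distribution and LGIN is empty (it is never diagnosed without
#' endoscopy).  In the screened arms the cancer states receive the
#' screening detection rate times the screening stage distribution and
#' LGIN receives the LGIN detection rate.  `NORMAL` takes the residual and
#' `DEATH` starts empty.
#'
#' @param strategy One of `NON_SCR`, `SCR_FOL`, `SCR_NFOL`.
#' @param band Starting band label (e.g. `"40-44"`) or a row of
#'   `params$age_rates`.
#' @param params An `ecscreen_params` object.
#' @return Named numeric vector of length 11 summing to 1.
#' @export
#' @examples
#' initial_state_vector("SCR_FOL", "40-44", base_case_fixture())
initial_state_vector <- function(strategy, band, params) {
  assert_strategy(strategy)
  if (is.character(band)) {
    i <- match(band, params$age_rates$band)
    if (is.na(i)) stop("unknown age band: ", band, call. = FALSE)
    band <- params$age_rates[i, ]
  }
  scale <- params$rate_scale
  v <- stats::setNames(numeric(11L), health_states())
  if (strategy == "NON_SCR") {
    ec <- band$ec_incidence / scale * stage_vec(params, "nonscreening")
    lgin <- 0
  } else {
    if (is.na(band$ec_detection) || is.na(band$lgin_detection)) {
      stop("band ", band$band, " has no screening detection rates; ",
           "screening arms start in bands 40-44 through 65-69",
           call. = FALSE)
    }
    ec <- band$ec_detection / scale * stage_vec(params, "screening")
    lgin <- band$lgin_detection / scale
  }
  v[c("IC", "SM", "MOD", "ADV")] <- ec
  v[["LGIN"]] <- lgin
  residual <- 1 - sum(v)
  if (residual < 0) {
    stop("initial cancer and LGIN occupancy exceeds 1 in band ", band$band,
         call. = FALSE)
  }
  v[["NORMAL"]] <- residual
  v
}

#' Annual cost of a disease-free state from a visit schedule
#'
#' The annual cost of a follow-up (disease-free) state is the annual number
#' of hospital visits times the average cost per visit, the latter being
#' the sum over examination items of item count times unit price.
#'
#' @param n_visits Annual number of hospital visits.
#' @param items A data frame or tibble with columns `count` (number of
#'   items) and `price` (USD per item).
#' @return Annual cost in USD.
#' @export
#' @examples
#' dfs_annual_cost(2, data.frame(count = c(1, 2), price = c(100, 50)))
dfs_annual_cost <- function(n_visits, items) {
  stopifnot(n_visits >= 0)
  if (nrow(items) == 0) return(0)
  stopifnot(all(c("count", "price") %in% names(items)),
            all(items$count >= 0), all(items$price >= 0))
  n_visits * sum(items$count * items$price)
}
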