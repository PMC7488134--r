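#' Build one row of the annual transition matrix
#'
#' Composes the outgoing annual transition probabilities of a health state
#' at a given attained age under a strategy.  Published "gross" transitions
#' into the disease-free / progression-free states are net of the
#' background death probability `d_nor` (the tables print them as, e.g.,
#' `0.9363 - d_nor`).  Rows are made stochastic death-first: the state's
#' total death probability (cancer-specific plus background for the
#' submucosal/invasive states and their survivor states; background alone
#' elsewhere) is allocated first, then the remaining transition masses are
#' scaled proportionally if they would exceed the residual `1 - death`;
#' any shortfall stays in-state.
#'
#' @param state Health-state name.
#' @param strategy Strategy name.
#' @param attained_age Age in years (must fall in a parameter age band).
#' @param params An `ecscreen_params` object.
#' @return Named numeric vector of length 11 summing to 1.  Attribute
#'   `ec_death_share` carries the portion of the `DEATH` entry
#'   attributable to the cancer-specific death probability.
#' @export
#' @examples
#' build_transition_row("IC", "NON_SCR", 42, base_case_fixture())
build_transition_row <- function(state, strategy, attained_age, params) {
  assert_state(state)
  assert_strategy(strategy)
  sc <- params$scalars
  band <- band_for_age(params, attained_age)
  d_nor <- background_death_prob(band, params$rate_scale)

  row <- stats::setNames(numeric(11L), health_states())
  if (state == "DEATH") {
    row[["DEATH"]] <- 1
    attr(row, "ec_death_share") <- 0
    return(row)
  }

  sv <- function(key) scalar_value(sc, key)
  split3 <- function(key) {
    comp <- sc[[key]]
    vapply(setdiff(names(comp), "dist"),
           function(k) as.numeric(comp[[k]]$value), 1)
  }

  ec_d <- if (state %in% ec_death_states()) {
    ec_death_prob(state, attained_age, sc)
  } else 0
  death <- min(ec_d + d_nor, 1)

  masses <- switch(
    state,
    NORMAL = {
      inc <- band$ec_incidence / params$rate_scale
      if (strategy != "NON_SCR") {
        inc <- adjusted_incidence(inc, sv("rr_screening"))
      }
      ec <- inc * stage_vec(params, "nonscreening")
      stats::setNames(as.numeric(ec), c("IC", "SM", "MOD", "ADV"))
    },
    LGIN = {
      lgin_inc <- band$ec_incidence_lgin / params$rate_scale
      scenario <- if (strategy == "SCR_FOL") "screening" else "nonscreening"
      ec <- lgin_inc * stage_vec(params, scenario)
      m <- stats::setNames(as.numeric(ec), c("IC", "SM", "MOD", "ADV"))
      if (strategy == "SCR_FOL") {
        m <- c(NORMAL = sv("lgin_to_normal"), m)
      }
      m
    },
    IC = {
      s <- split3("ic_progress_split")
      c(DFS_IC = sv("ic_to_dfs_gross") - d_nor,
        SM = sv("ic_progress") * s[["sm"]],
        MOD = sv("ic_progress") * s[["mod"]],
        ADV = sv("ic_progress") * s[["adv"]])
    },
    SM = {
      s <- split3("sm_progress_split")
      c(DFS_SM = sv("sm_to_dfs_gross") - d_nor,
        MOD = sv("sm_progress") * s[["mod"]],
        ADV = sv("sm_progress") * s[["adv"]])
    },
    MOD = c(DFS_MOD = sv("mod_to_dfs_gross") - d_nor,
            ADV = sv("mod_to_adv")),
    ADV = c(PFS_ADV = sv("adv_to_pfs_gross") - d_nor),
    DFS_IC = {
      s <- split3("dfs_ic_progress_split")
      c(IC = sv("dfs_ic_to_ic"),
        SM = sv("dfs_ic_progress") * s[["sm"]],
        MOD = sv("dfs_ic_progress") * s[["mod"]],
        ADV = sv("dfs_ic_progress") * s[["adv"]])
    },
    DFS_SM = {
      s <- split3("sm_progress_split")
      c(SM = sv("dfs_sm_to_sm"),
        MOD = sv("dfs_sm_progress") * s[["mod"]],
        ADV = sv("dfs_sm_progress") * s[["adv"]])
    },
    DFS_MOD = c(MOD = sv("dfs_mod_to_mod"),
                ADV = sv("dfs_mod_to_adv")),
    PFS_ADV = c(ADV = sv("pfs_progress"))
  )

  if (any(masses < 0)) {
    bad <- names(masses)[masses < 0]
    stop("negative transition probability out of ", state, " at age ",
         attained_age, " (background death exceeds gross transition to ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }

  avail <- 1 - death
  total <- sum(masses)
  if (total > avail) {
    masses <- masses * (avail / total)
    stay <- 0
  } else {
    stay <- avail - total
  }
  row[names(masses)] <- masses
  row[[state]] <- row[[state]] + stay
  row[["DEATH"]] <- death
  attr(row, "ec_death_share") <-
    if (ec_d + d_nor > 0) death * ec_d / (ec_d + d_nor) else 0
  row
}

#' Build the full annual transition matrix
#'
#' Assembles the 11 x 11 row-stochastic transition matrix for a strategy
#' at an attained age, with `DEATH` absorbing.
#'
#' @inheritParams build_transition_row
#' @return An 11 x 11 matrix with state dimnames; attributes `strategy`,
#'   `attained_age` and `ec_death_share` (per-state cancer-specific death
#'   mass, used by the trace counters).
#' @export
build_transition_matrix <- function(strategy, attained_age, params) {
  states <- health_states()
  rows <- lapply(states, build_transition_row, strategy = strategy,
                 attained_age = attained_age, params = params)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(states, states)
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-12)) {
    stop("transition matrix rows do not sum to 1 at age ", attained_age,
         call. = FALSE)
  }
  attr(m, "strategy") <- strategy
  attr(m, "attained_age") <- attained_age
  attr(m, "ec_death_share") <-
    stats::setNames(vapply(rows, function(r) attr(r, "ec_death_share"), 1),
                    states)
  m
}

#' Run the cohort simulation for one strategy and starting age band
#'
#' Simulates the deterministic (expected-value) cohort from the starting
#' occupancy produced by [initial_state_vector()] until the attained age
#' passes the horizon (79 years).  Each cycle applies the transition matrix
#' of the band containing the attained age.  The trace records per-cycle
#' occupancy (in persons), newly incident cancer cases (transitions from
#' `NORMAL` or `LGIN` into a cancer state) and deaths occurring through
#' the cancer-specific death probabilities.
#'
#' @param params An `ecscreen_params` object.
#' @param strategy Strategy name.
#' @param start_band Starting band label, one of the screened bands
#'   (`"40-44"` ... `"65-69"`).
#' @param attained_age_convention `"midpoint"` (default) ages the cohort
#'   from the band midpoint (lower bound + 2); `"lower"` uses the lower
#'   bound.
#' @param include_baseline_cases Count the prevalent/detected cancer cases
#'   of cycle 0 in the incident-case tally.  The default `FALSE` counts
#'   post-baseline incident cases only, which is how the published
#'   cumulative-incidence tables behave (the screened arms' cumulative
#'   incidence sits below their baseline detection rate); set `TRUE` for a
#'   like-for-like tally that also charges detected prevalence to the
#'   screened arms.
#' @return A `cohort_trace`: a tibble with columns `cycle`, `attained_age`,
#'   one occupancy column per state, `new_ec_cases` and `ec_deaths`
#'   (events during the transition into the row's cycle).
#' @export
#' @examples
#' tr <- run_cohort(base_case_fixture(), "NON_SCR", "40-44")
#' cumulative_ec_incidence(tr)
run_cohort <- function(params, strategy, start_band,
                       attained_age_convention = c("midpoint", "lower"),
                       include_baseline_cases = FALSE) {
  assert_strategy(strategy)
  attained_age_convention <- match.arg(attained_age_convention)
  i <- match(start_band, params$age_rates$band)
  if (is.na(i)) stop("unknown age band: ", start_band, call. = FALSE)
  band <- params$age_rates[i, ]
  if (!start_band %in% start_bands(params)) {
    stop("start band must be a screened band (",
         paste(range(start_bands(params)), collapse = " ... "), ")",
         call. = FALSE)
  }

  offset <- if (attained_age_convention == "midpoint") 2 else 0
  start_age <- band$lower + offset
  ages <- seq(start_age, params$econ$horizon_age)
  cohort <- params$econ$cohort_size
  states <- health_states()

  v <- cohort * initial_state_vector(strategy, start_band, params)
  n_cycles <- length(ages)
  occ <- matrix(0, nrow = n_cycles + 1L, ncol = 11L,
                dimnames = list(NULL, states))
  occ[1L, ] <- v
  new_cases <- numeric(n_cycles + 1L)
  ec_deaths <- numeric(n_cycles + 1L)
  if (include_baseline_cases) {
    new_cases[1L] <- sum(v[ec_states()])
  }

  cache <- list()
  for (k in seq_along(ages)) {
    age <- ages[k]
    b <- band_for_age(params, age)
    key <- paste(b$band, age > 65)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_transition_matrix(strategy, age, params)
    }
    M <- cache[[key]]
    share <- attr(M, "ec_death_share")
    sources <- c("NORMAL", "LGIN")
    new_cases[k + 1L] <- sum(v[sources] %*% M[sources, ec_states()])
    ec_deaths[k + 1L] <- sum(v * share)
    v <- as.numeric(v %*% M)
    names(v) <- states
    occ[k + 1L, ] <- v
  }

  trace <- dplyr::bind_cols(
    tibble(cycle = 0:n_cycles,
           attained_age = c(ages, params$econ$horizon_age + 1)),
    as_tibble(occ),
    tibble(new_ec_cases = new_cases, ec_deaths = ec_deaths)
  )
  structure(trace,
            class = c("cohort_trace", class(trace)),
            strategy = strategy,
            start_band = start_band,
            cohort_size = cohort,
            attained_age_convention = attained_age_convention,
            include_baseline_cases = include_baseline_cases)
}

#' Cumulative cancer incidence and mortality of a trace
#'
#' `cumulative_ec_incidence()` totals the incident-case counter (plus the
#' cycle-0 prevalent/detected cases when the trace was run with
#' `include_baseline_cases = TRUE`) and rescales to per 100,000.
#' `cumulative_ec_mortality()` does the same for deaths attributed to the
#' cancer-specific death probabilities.
#'
#' @param trace A `cohort_trace`.
#' @return A single number per 100,000 cohort members.
#' @export
cumulative_ec_incidence <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$new_ec_cases) / attr(trace, "cohort_size") * 1e5
}

#' @rdname cumulative_ec_incidence
#' @export
cumulative_ec_mortality <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$ec_deaths) / attr(trace, "cohort_size") * 1e5
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", attr(x, "strategy"), ", start band ",
      attr(x, "start_band"), ", ", nrow(x) - 1L, " transitions\n", sep = "")
  NextMethod()
}

#' Plot cohort occupancy over time
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object: occupancy by state across cycles.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(health_states()),
                              names_to = "state", values_to = "persons")
  long$state <- factor(long$state, levels = health_states())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$persons,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (years)", y = "Persons",
                  title = paste0(attr(object, "strategy"), ", start band ",
                                 attr(object, "start_band")))
}
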