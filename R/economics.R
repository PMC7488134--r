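#' Discounting and inflation
#'
#' Costs and QALYs accruing in cycle `t` are discounted by
#' `(1 + rate)^-t`; cost items additionally inflate at the medical
#' inflation rate, `base * (1 + inflation)^t`.  In the base case both
#' rates apply to costs (5% discount, 4.7% inflation) while QALYs are
#' discounted only.
#'
#' @param cycle Cycle index (years since baseline), `>= 0`.
#' @param rate Annual discount rate.
#' @param base Undiscounted cost in USD.
#' @param inflation Annual inflation rate.
#' @return `discount_factor()`: a multiplier; `inflated_cost()`: USD.
#' @export
#' @examples
#' discount_factor(1, 0.05)
#' inflated_cost(100, 2, 0.047)
discount_factor <- function(cycle, rate) {
  stopifnot(all(cycle >= 0))
  (1 + rate)^(-cycle)
}

#' @rdname discount_factor
#' @export
inflated_cost <- function(base, cycle, inflation) {
  stopifnot(all(base >= 0), all(cycle >= 0))
  base * (1 + inflation)^cycle
}

# Per-state annual cost vector for a strategy, by cycle position.
state_cost_vector <- function(params, strategy, cycle) {
  cost <- params$costs$treatment
  # Annual follow-up endoscopy for LGIN exists only in the follow-up arm;
  # without follow-up the LGIN management cost applies at diagnosis only.
  if (strategy == "SCR_NFOL" && cycle > 0) cost[["LGIN"]] <- 0
  if (strategy == "NON_SCR") cost[["LGIN"]] <- 0
  cost
}

#' Discounted costs and QALYs of a cohort trace
#'
#' Accrues costs and quality-adjusted life-years on start-of-cycle
#' occupancy over the lived cycles of a trace (no half-cycle correction).
#' The one-time screening cost applies to the cycle-0 occupancy of the
#' screened arms only; state treatment and follow-up costs accrue per year
#' spent in the state, inflated and discounted; utilities are discounted
#' only.
#'
#' @param trace A `cohort_trace`.
#' @param params An `ecscreen_params` object.
#' @return An `econ_outcome`: list with `strategy`, `start_band`,
#'   `total_cost` (USD, discounted), `total_qalys` (QALY-years,
#'   discounted) and a per-cycle tibble `cycles`.
#' @export
#' @examples
#' p <- base_case_fixture()
#' accumulate_outcomes(run_cohort(p, "NON_SCR", "40-44"), p)
accumulate_outcomes <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"))
  strategy <- attr(trace, "strategy")
  e <- params$econ
  states <- health_states()
  occ <- as.matrix(as_tibble(trace)[, states])
  n_lived <- nrow(occ) - 1L  # terminal row is a snapshot, not a lived year
  util <- stats::setNames(params$utilities$mean, params$utilities$state)[states]

  cycles <- purrr::map_dfr(seq_len(n_lived), function(i) {
    t <- i - 1L
    v <- occ[i, ]
    cost_vec <- state_cost_vector(params, strategy, t)[states]
    nominal <- sum(v * cost_vec)
    if (t == 0L && strategy != "NON_SCR") {
      nominal <- nominal + sum(v * params$costs$screening[states])
    }
    disc <- discount_factor(t, e$discount_rate)
    tibble(cycle = t,
           cost = inflated_cost(nominal, t, e$inflation_rate) * disc,
           qalys = sum(v * util) * disc)
  })

  structure(
    list(strategy = strategy,
         start_band = attr(trace, "start_band"),
         total_cost = sum(cycles$cost),
         total_qalys = sum(cycles$qalys),
         cycles = cycles),
    class = "econ_outcome"
  )
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat("<econ_outcome> ", x$strategy, ", start band ", x$start_band, "\n",
      sep = "")
  cat(sprintf("  cost %.2f million USD, %.2f thousand QALYs\n",
              x$total_cost / 1e6, x$total_qalys / 1e3))
  invisible(x)
}

#' @export
tidy.econ_outcome <- function(x, ...) {
  dplyr::mutate(x$cycles, strategy = x$strategy,
                start_band = x$start_band, .before = 1)
}

#' @export
glance.econ_outcome <- function(x, ...) {
  tibble(strategy = x$strategy, start_band = x$start_band,
         total_cost = x$total_cost, total_qalys = x$total_qalys)
}

outcome_row <- function(x) {
  if (inherits(x, "econ_outcome")) {
    tibble(strategy = x$strategy, cost = x$total_cost, qalys = x$total_qalys)
  } else {
    as_tibble(x)
  }
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qalys_a - qalys_b)`, in USD per QALY.  The sign is
#' preserved: a negative value means strategy `a` saves money while gaining
#' QALYs (or costs more while losing them) relative to `b`.  Equal
#' effectiveness yields `NA` (the undefined-ICER signal), never an error.
#'
#' @param a,b `econ_outcome` objects, or lists/one-row data frames with
#'   elements `cost` and `qalys`.
#' @return USD per QALY, or `NA` when the QALY difference is zero.
#' @export
icer <- function(a, b) {
  a <- if (is.list(a) && !is.data.frame(a) && !inherits(a, "econ_outcome"))
    tibble(cost = a$cost, qalys = a$qalys) else outcome_row(a)
  b <- if (is.list(b) && !is.data.frame(b) && !inherits(b, "econ_outcome"))
    tibble(cost = b$cost, qalys = b$qalys) else outcome_row(b)
  dq <- a$qalys - b$qalys
  if (dq == 0) return(NA_real_)
  (a$cost - b$cost) / dq
}

#' Dominance analysis over a set of strategies
#'
#' Standard incremental cost-effectiveness analysis: strategies are sorted
#' by cost; any strategy at least as costly and no more effective than
#' another (one comparison strict) is absolutely dominated; among the
#' rest, strategies whose incremental ICER exceeds that of the next more
#' expensive option are removed by extended dominance, iteratively, so
#' the remaining frontier has strictly increasing ICERs.
#'
#' @param outcomes A tibble with columns `strategy`, `cost`, `qalys`, or a
#'   list of `econ_outcome` objects.
#' @return A `ce_result` tibble sorted by cost with columns `strategy`,
#'   `cost`, `qalys`, `label` (one of `undominated`,
#'   `absolutely_dominated`, `extended_dominated`) and `icer` (frontier
#'   incremental ICER versus the next cheaper frontier strategy; `NA` off
#'   the frontier and for the cheapest option).
#' @export
#' @examples
#' dominance_analysis(tibble::tibble(
#'   strategy = c("A", "B", "C"),
#'   cost = c(40.52e6, 44.85e6, 45.29e6),
#'   qalys = c(1437.30e3, 1436.15e3, 1437.07e3)))
dominance_analysis <- function(outcomes) {
  if (is.list(outcomes) && !is.data.frame(outcomes)) {
    outcomes <- purrr::map_dfr(outcomes, outcome_row)
  }
  stopifnot(all(c("strategy", "cost", "qalys") %in% names(outcomes)),
            nrow(outcomes) >= 2)
  df <- dplyr::arrange(as_tibble(outcomes), .data$cost, dplyr::desc(.data$qalys))
  n <- nrow(df)

  label <- rep("undominated", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dominated <- any(
      df$cost[others] <= df$cost[i] & df$qalys[others] >= df$qalys[i] &
        (df$cost[others] < df$cost[i] | df$qalys[others] > df$qalys[i]))
    if (dominated) label[i] <- "absolutely_dominated"
  }

  frontier <- which(label == "undominated")
  repeat {
    if (length(frontier) < 3) break
    icers <- vapply(seq_along(frontier)[-1], function(j) {
      icer(df[frontier[j], ], df[frontier[j - 1L], ])
    }, 1)
    worse <- which(diff(icers) < 0)  # ICER drops => previous step ext. dominated
    if (length(worse) == 0) break
    drop <- frontier[worse[1] + 1L]
    label[drop] <- "extended_dominated"
    frontier <- setdiff(frontier, drop)
  }

  df$label <- label
  df$icer <- NA_real_
  if (length(frontier) > 1) {
    for (j in seq_along(frontier)[-1]) {
      df$icer[frontier[j]] <- icer(df[frontier[j], ], df[frontier[j - 1L], ])
    }
  }
  structure(df, class = c("ce_result", class(df)))
}

#' @export
tidy.ce_result <- function(x, ...) as_tibble(x)

#' @export
glance.ce_result <- function(x, ...) {
  tibble(n_strategies = nrow(x),
         n_frontier = sum(x$label == "undominated"),
         best = x$strategy[x$label == "undominated"][
           sum(x$label == "undominated")])
}

#' Percent reduction of a rate relative to a comparator
#'
#' `(b - a) / b * 100`: positive when `a` is lower than the baseline `b`.
#'
#' @param metric_a Rate under the strategy of interest (per 100,000).
#' @param metric_b Baseline rate (per 100,000), `> 0`.
#' @return Percent reduction (negative for an increase).
#' @export
#' @examples
#' reduction_vs(708.61, 1010.62)
reduction_vs <- function(metric_a, metric_b) {
  if (any(metric_b <= 0)) {
    stop("baseline metric must be positive", call. = FALSE)
  }
  (metric_b - metric_a) / metric_b * 100
}
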