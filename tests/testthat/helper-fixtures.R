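# Shared fixtures: the packaged base case plus cached cohort runs so the
# suite re-uses expensive simulations instead of recomputing them.

bc <- base_case_fixture()

.run_cache <- new.env(parent = emptyenv())

bc_trace <- function(strategy, band, ...) {
  key <- paste(strategy, band, ...)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_cohort(bc, strategy, band, ...)
  }
  .run_cache[[key]]
}

bc_econ <- function(strategy, band) {
  key <- paste("econ", strategy, band)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- accumulate_outcomes(bc_trace(strategy, band), bc)
  }
  .run_cache[[key]]
}

# Minimal hand-made trace (for economics accrual checks): occupancy given
# as a list of named state vectors, one per cycle, plus a terminal row.
toy_trace <- function(rows, strategy = "NON_SCR", cohort_size = NULL) {
  states <- health_states()
  occ <- matrix(0, nrow = length(rows), ncol = 11,
                dimnames = list(NULL, states))
  for (i in seq_along(rows)) occ[i, names(rows[[i]])] <- rows[[i]]
  tr <- dplyr::bind_cols(
    tibble::tibble(cycle = seq_along(rows) - 1L,
                   attained_age = 60 + seq_along(rows) - 1L),
    tibble::as_tibble(occ),
    tibble::tibble(new_ec_cases = 0, ec_deaths = 0))
  structure(tr, class = c("cohort_trace", class(tr)),
            strategy = strategy, start_band = "55-59",
            cohort_size = cohort_size %||% sum(occ[1, ]),
            attained_age_convention = "midpoint",
            include_baseline_cases = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent dominance oracle: absolute dominance by pairwise comparison,
# extended dominance by blending -- a strategy is off the frontier iff some
# convex combination of two others costs no more and yields no fewer QALYs.
brute_force_dominance <- function(df) {
  n <- nrow(df)
  lab <- rep("undominated", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i] &&
          (df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i])) {
        lab[i] <- "absolutely_dominated"
      }
    }
  }
  for (i in which(lab == "undominated")) {
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == i || b == i || a == b) next
      dq <- df$qalys[b] - df$qalys[a]
      if (dq == 0) next
      lambda <- (df$qalys[b] - df$qalys[i]) / dq
      if (lambda < 0 || lambda > 1) next
      blend_cost <- lambda * df$cost[a] + (1 - lambda) * df$cost[b]
      if (blend_cost < df$cost[i] - 1e-9) lab[i] <- "extended_dominated"
    }
  }
  lab
}
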