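#' Fit a sampling distribution to a published parameter
#'
#' Method-of-moments fits for the distribution families used in the
#' probabilistic sensitivity analysis: beta for probabilities and
#' utilities, gamma for costs, Dirichlet for stage simplexes, lognormal
#' for risk ratios (median anchored at the point estimate) and triangular
#' for the discount and inflation rates.  Parameters published with a
#' plausible range but no SD are given `sd = (hi - lo) / (2 * 1.96)`,
#' treating the range as a central 95% interval.
#'
#' @param mean Central value (a simplex vector for `dirichlet`; the mode
#'   for `triangular`).
#' @param sd Standard deviation (beta, gamma); `NULL` to derive from
#'   `range`.
#' @param range Length-2 plausible range `c(lo, hi)`.
#' @param family One of `"beta"`, `"gamma"`, `"dirichlet"`, `"lognormal"`,
#'   `"triangular"`.
#' @param ess Effective sample size for Dirichlet concentrations
#'   (default 100).
#' @return A `dist_spec` list with the family, its hyperparameters and the
#'   provenance used to fit them.  An `sd` of zero yields a degenerate
#'   point mass.
#' @export
#' @examples
#' fit_distribution(0.852, sd = 0.029, family = "beta")
fit_distribution <- function(mean, sd = NULL, range = NULL,
                             family = c("beta", "gamma", "dirichlet",
                                        "lognormal", "triangular"),
                             ess = 100) {
  family <- match.arg(family)
  if (is.null(sd) && !is.null(range) && family %in% c("beta", "gamma")) {
    sd <- (range[2] - range[1]) / (2 * 1.96)
  }
  spec <- switch(
    family,
    beta = {
      if (sd == 0) {
        list(degenerate = TRUE, value = mean)
      } else {
        if (mean <= 0 || mean >= 1) {
          stop("beta mean must lie in (0, 1)", call. = FALSE)
        }
        v <- sd^2
        nu <- mean * (1 - mean) / v - 1
        if (nu <= 0) {
          stop("beta fit infeasible: SD ", sd, " too large for mean ", mean,
               call. = FALSE)
        }
        list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
      }
    },
    gamma = {
      if (mean == 0 || sd == 0) {
        list(degenerate = TRUE, value = mean)
      } else {
        if (mean < 0) stop("gamma mean must be non-negative", call. = FALSE)
        list(shape = mean^2 / sd^2, rate = mean / sd^2)
      }
    },
    dirichlet = {
      if (abs(sum(mean) - 1) > 1e-6 || any(mean < 0)) {
        stop("dirichlet mean must be a simplex", call. = FALSE)
      }
      list(alpha = mean * ess)
    },
    lognormal = {
      if (is.null(range)) stop("lognormal fit needs a range", call. = FALSE)
      if (mean <= 0 || any(range <= 0)) {
        stop("lognormal needs positive mean and range", call. = FALSE)
      }
      list(meanlog = log(mean),
           sdlog = (log(range[2]) - log(range[1])) / (2 * 1.96))
    },
    triangular = {
      if (is.null(range)) stop("triangular fit needs a range", call. = FALSE)
      if (!(range[1] <= mean && mean <= range[2])) {
        stop("triangular mode must lie inside the range", call. = FALSE)
      }
      list(min = range[1], mode = mean, max = range[2])
    }
  )
  structure(list(family = family, params = spec, mean = mean,
                 provenance = list(sd = sd, range = range, ess = ess)),
            class = "dist_spec")
}

rtriangular <- function(n, min, mode, max) {
  if (min == max) return(rep(min, n))
  u <- stats::runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

rdirichlet <- function(n, alpha) {
  g <- vapply(alpha, function(a) {
    if (a > 0) stats::rgamma(n, shape = a) else numeric(n)
  }, numeric(n))
  g <- matrix(g, nrow = n)
  out <- g / rowSums(g)
  colnames(out) <- names(alpha)
  out
}

#' Draw from a fitted distribution
#'
#' @param spec A `dist_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return A numeric vector of length `n`, or an `n` x k matrix for
#'   Dirichlet specs.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  if (isTRUE(p$degenerate)) {
    if (spec$family == "dirichlet") stop("unreachable", call. = FALSE)
    return(rep(p$value, n))
  }
  switch(spec$family,
         beta = stats::rbeta(n, p$shape1, p$shape2),
         gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         triangular = rtriangular(n, p$min, p$mode, p$max),
         dirichlet = rdirichlet(n, p$alpha))
}

# ---- parameter registry -------------------------------------------------

reg_entry <- function(id, family, mean, sd = NULL, range = NULL,
                      setter, ess = 100, one_way = TRUE) {
  list(id = id, family = family, mean = mean, sd = sd, range = range,
       ess = ess, setter = setter, one_way = one_way)
}

set_scalar <- function(key) {
  force(key)
  function(params, value) {
    params$scalars[[key]]$value <- min(max(value, 0), 1)
    params
  }
}

set_nested <- function(group, key, lo = 0, hi = 1) {
  force(group); force(key); force(lo); force(hi)
  function(params, value) {
    params$scalars[[group]][[key]]$value <- min(max(value, lo), hi)
    params
  }
}

set_rate <- function(band_idx, col) {
  force(band_idx); force(col)
  function(params, value) {
    params$age_rates[[col]][band_idx] <- max(value, 0)
    params
  }
}

set_cost <- function(state) {
  force(state)
  function(params, value) {
    params$costs$treatment[[state]] <- max(value, 0)
    params
  }
}

set_util <- function(state) {
  force(state)
  function(params, value) {
    params$utilities$mean[params$utilities$state == state] <-
      min(max(value, 0), 1)
    params
  }
}

#' Registry of uncertain parameters
#'
#' Enumerates every parameter varied in the sensitivity analyses with its
#' base value, plausible range, PSA distribution family and a setter that
#' writes a new value back into a parameter set (with the documented
#' clamping: probabilities and utilities to `[0, 1]`, costs and rates to
#' non-negative, elderly risk ratios to at least 1).  Probabilities,
#' utilities, rates and risk ratios carry a +/-20% range unless a table
#' prints one; costs carry +/-30%; the discount rate spans 0--8% and the
#' inflation rate 3.2--6.2%.
#'
#' @param params An `ecscreen_params` object.
#' @return A list of registry entries (used by [sample_parameters()] and
#'   [one_way_sa()]).
#' @export
parameter_registry <- function(params) {
  sc <- params$scalars
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  add(reg_entry("discount_rate", "triangular", params$econ$discount_rate,
                range = c(0, 0.08),
                setter = function(p, v) { p$econ$discount_rate <- v; p }))
  add(reg_entry("inflation_rate", "triangular", params$econ$inflation_rate,
                range = c(0.032, 0.062),
                setter = function(p, v) { p$econ$inflation_rate <- v; p }))

  # one-time screening cost (same endoscopy price on every screened state)
  scr_cost <- max(params$costs$screening)
  add(reg_entry("cost_screening", "gamma", scr_cost,
                range = scr_cost * c(0.7, 1.3),
                setter = function(p, v) {
                  v <- max(v, 0)
                  p$costs$screening[p$costs$screening > 0] <- v
                  p
                }))
  for (s in setdiff(health_states(), c("NORMAL", "DEATH"))) {
    base <- params$costs$treatment[[s]]
    if (base > 0) {
      add(reg_entry(paste0("cost_", s), "gamma", base,
                    range = base * c(1 - params$costs$sa_fraction,
                                     1 + params$costs$sa_fraction),
                    setter = set_cost(s)))
    }
  }

  for (s in setdiff(health_states(), c("NORMAL", "DEATH"))) {
    u <- params$utilities[params$utilities$state == s, ]
    add(reg_entry(paste0("util_", s), "beta", u$mean, sd = u$sd,
                  range = c(u$sa_lo, u$sa_hi), setter = set_util(s)))
  }

  prob_keys <- c("lgin_to_normal", "ic_to_dfs_gross", "ic_progress",
                 "dfs_ic_to_ic", "dfs_ic_progress", "sm_to_dfs_gross",
                 "sm_progress", "dfs_sm_to_sm", "dfs_sm_progress",
                 "mod_to_dfs_gross", "mod_to_adv", "dfs_mod_to_mod",
                 "dfs_mod_to_adv", "adv_to_pfs_gross", "pfs_progress")
  for (k in prob_keys) {
    e <- sc[[k]]
    add(reg_entry(k, "beta", as.numeric(e$value),
                  range = as.numeric(unlist(e$sa_range)),
                  setter = set_scalar(k)))
  }
  add(reg_entry("rr_screening", "lognormal",
                as.numeric(sc$rr_screening$value),
                range = as.numeric(unlist(sc$rr_screening$sa_range)),
                setter = function(p, v) {
                  p$scalars$rr_screening$value <- max(v, 1e-12); p
                }))
  for (k in names(sc$ec_death)) {
    e <- sc$ec_death[[k]]
    add(reg_entry(paste0("ec_death_", k), "beta", as.numeric(e$value),
                  range = as.numeric(unlist(e$sa_range)),
                  setter = set_nested("ec_death", k)))
  }
  for (k in names(sc$elderly_death_rr)) {
    e <- sc$elderly_death_rr[[k]]
    add(reg_entry(paste0("elderly_death_rr_", k), "lognormal",
                  as.numeric(e$value),
                  range = as.numeric(unlist(e$sa_range)),
                  setter = set_nested("elderly_death_rr", k, lo = 1,
                                      hi = Inf)))
  }

  # progression splits and stage simplexes: Dirichlet in the PSA;
  # one-way handling perturbs single components with renormalization.
  add(reg_entry("ic_progress_split", "dirichlet",
                split_values(sc$ic_progress_split),
                setter = set_split("ic_progress_split"), one_way = FALSE))
  add(reg_entry("dfs_ic_progress_split", "dirichlet",
                split_values(sc$dfs_ic_progress_split),
                setter = set_split("dfs_ic_progress_split"),
                one_way = FALSE))
  add(reg_entry("sm_progress_split", "dirichlet",
                split_values(sc$sm_progress_split),
                setter = set_split("sm_progress_split"), one_way = FALSE))
  add(reg_entry("stage_nonscreening", "dirichlet",
                params$stage$nonscreening,
                setter = function(p, v) { p$stage$nonscreening <- v; p },
                one_way = FALSE))
  add(reg_entry("stage_screening", "dirichlet", params$stage$screening,
                setter = function(p, v) { p$stage$screening <- v; p },
                one_way = FALSE))

  rate_cols <- c("ec_incidence", "ec_incidence_lgin", "ec_detection",
                 "lgin_detection", "ec_mortality", "all_cause_mortality")
  for (i in seq_len(nrow(params$age_rates))) {
    for (col in rate_cols) {
      base <- params$age_rates[[col]][i]
      if (is.na(base)) next
      add(reg_entry(paste0(col, "_", params$age_rates$band[i]), "rate_beta",
                    base, range = base * c(0.8, 1.2),
                    setter = set_rate(i, col)))
    }
  }
  entries
}

split_values <- function(split) {
  keys <- setdiff(names(split), "dist")
  stats::setNames(vapply(keys, function(k) as.numeric(split[[k]]$value), 1),
                  keys)
}

set_split <- function(key) {
  force(key)
  function(params, value) {
    for (k in names(value)) params$scalars[[key]][[k]]$value <- value[[k]]
    params
  }
}

registry_spec <- function(e, rate_scale = 1e5) {
  if (e$family == "rate_beta") {
    # printed per-100,000 rate: beta on the per-person probability scale
    if (e$mean == 0) return(fit_distribution(0, sd = 0, family = "beta"))
    fit_distribution(e$mean / rate_scale,
                     sd = (e$range[2] - e$range[1]) / (2 * 1.96) / rate_scale,
                     family = "beta")
  } else if (e$family == "beta" && !is.null(e$sd) && e$sd == 0) {
    fit_distribution(e$mean, sd = 0, family = "beta")
  } else if (e$family == "dirichlet") {
    fit_distribution(e$mean, family = "dirichlet", ess = e$ess)
  } else {
    fit_distribution(e$mean, sd = e$sd, range = e$range, family = e$family)
  }
}

draw_entry <- function(e, rate_scale = 1e5) {
  spec <- registry_spec(e, rate_scale)
  d <- sample_dist(spec, 1)
  if (e$family == "dirichlet") d <- drop(d)
  if (e$family == "rate_beta") d <- d * rate_scale
  d
}

#' Draw a validated parameter set for the PSA
#'
#' Samples every registry parameter from its fitted distribution, writes
#' the draws into a copy of the base parameter set (with documented
#' clamping) and validates the result.  Invalid draws are resampled up to
#' `max_retries` times.
#'
#' @param base An `ecscreen_params` object.
#' @param registry Output of [parameter_registry()] (rebuilt from `base`
#'   when `NULL`).
#' @param rng_seed Optional integer seed; `NULL` uses the current RNG
#'   state (what [run_psa()] does across iterations).
#' @param max_retries Resampling attempts before giving up.
#' @return A validated `ecscreen_params` draw.
#' @export
#' @examples
#' p <- sample_parameters(base_case_fixture(), rng_seed = 1)
#' p$scalars$rr_screening$value
sample_parameters <- function(base, registry = NULL, rng_seed = NULL,
                              max_retries = 20) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(registry)) registry <- parameter_registry(base)
  for (attempt in seq_len(max_retries)) {
    draw <- base
    for (e in registry) {
      draw <- e$setter(draw, draw_entry(e, base$rate_scale))
    }
    ok <- tryCatch({
      draw <- suppressWarnings(validate_parameters(draw))
      TRUE
    }, error = function(err) FALSE)
    if (ok) return(draw)
  }
  stop("could not draw a valid parameter set after ", max_retries,
       " attempts", call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Propagates joint parameter uncertainty through the whole pipeline: for
#' each Monte-Carlo iteration a parameter set is drawn with
#' [sample_parameters()], the cohort model is re-run for every strategy
#' for one starting age band, and the discounted cost and QALY totals are
#' recorded.
#'
#' @param params Base `ecscreen_params`.
#' @param n_iter Number of iterations (the headline analysis uses 100,000;
#'   2,000 is a practical fast setting).
#' @param seed Integer RNG seed.
#' @param band Starting age band.
#' @param strategies Strategy arms to evaluate.
#' @return A `psa_result`: list with the per-iteration tibble `draws`
#'   (`iteration`, `strategy`, `cost`, `qalys`), `n_iter`, `seed`, `band`,
#'   `cohort_size` and the count of `failed` draws (excluded and logged).
#' @export
run_psa <- function(params, n_iter, seed, band = "40-44",
                    strategies = c("NON_SCR", "SCR_FOL", "SCR_NFOL")) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  registry <- parameter_registry(params)
  failed <- 0L
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    draw <- tryCatch(sample_parameters(params, registry),
                     error = function(e) NULL)
    if (is.null(draw)) {
      failed <- failed + 1L
      next
    }
    rows[[it]] <- purrr::map_dfr(strategies, function(s) {
      out <- accumulate_outcomes(run_cohort(draw, s, band), draw)
      tibble(iteration = it, strategy = s,
             cost = out$total_cost, qalys = out$total_qalys)
    })
  }
  if (failed > 0) {
    warning(failed, " parameter draw(s) failed validation and were excluded",
            call. = FALSE)
  }
  structure(list(draws = dplyr::bind_rows(rows), n_iter = n_iter,
                 seed = seed, band = band,
                 cohort_size = params$econ$cohort_size,
                 wtp = params$econ$wtp, failed = failed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_iter, " iterations, band ", x$band,
      ", seed ", x$seed, ", ", x$failed, " failed draws\n", sep = "")
  invisible(x)
}

#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @export
glance.psa_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$draws, .data$strategy),
                   mean_cost = mean(.data$cost),
                   mean_qalys = mean(.data$qalys), .groups = "drop")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy maximizes net monetary benefit
#' `wtp * QALYs - cost`.  Ties split their weight equally, so the
#' fractions sum to one at every threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay values (USD/QALY).
#' @return A `ceac_df` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) > 0)
  wide_c <- tidyr::pivot_wider(psa$draws, id_cols = "iteration",
                               names_from = "strategy",
                               values_from = "cost")
  wide_q <- tidyr::pivot_wider(psa$draws, id_cols = "iteration",
                               names_from = "strategy",
                               values_from = "qalys")
  strats <- setdiff(names(wide_c), "iteration")
  cm <- as.matrix(wide_c[, strats])
  qm <- as.matrix(wide_q[, strats])
  out <- purrr::map_dfr(wtp_grid, function(lambda) {
    nmb <- lambda * qm - cm
    best <- nmb == matrixStats_rowMaxs(nmb)
    w <- best / rowSums(best)  # split ties equally
    tibble(wtp = lambda, strategy = strats,
           probability = unname(colMeans(w)))
  })
  structure(out, class = c("ceac_df", class(out)))
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) {
  apply(m, 1, max)
}

#' @export
autoplot.ceac_df <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves")
}

#' Cost-effectiveness plane with confidence ellipse
#'
#' Computes per-person incremental cost and effectiveness pairs of a
#' strategy against a reference across PSA iterations, the quadrant
#' shares, and the bivariate-normal confidence ellipse (mean plus
#' covariance scaled by the chi-square quantile at `level`).
#'
#' @param psa A `psa_result`.
#' @param strategy Strategy of interest.
#' @param ref Reference strategy.
#' @param level Coverage level of the ellipse (default 0.95).
#' @return A `ce_plane` list: `points` (tibble `delta_cost`,
#'   `delta_qalys` per person), `center`, `cov`, `radius2`
#'   (`qchisq(level, 2)`), `ellipse` (a closed path tibble for plotting),
#'   `quadrants` (share of points per quadrant) and `degenerate` (`TRUE`
#'   when the covariance is singular and the ellipse has zero area).
#' @export
ce_plane_ellipse <- function(psa, strategy, ref = "NON_SCR", level = 0.95) {
  stopifnot(inherits(psa, "psa_result"))
  draws <- psa$draws
  a <- draws[draws$strategy == strategy, ]
  b <- draws[draws$strategy == ref, ]
  stopifnot(nrow(a) >= 3, nrow(a) == nrow(b))
  pts <- tibble(
    delta_cost = (a$cost - b$cost) / psa$cohort_size,
    delta_qalys = (a$qalys - b$qalys) / psa$cohort_size
  )
  center <- c(delta_qalys = mean(pts$delta_qalys),
              delta_cost = mean(pts$delta_cost))
  S <- stats::cov(cbind(pts$delta_qalys, pts$delta_cost))
  degenerate <- !is.finite(determinant(S)$modulus) || det(S) <= 0
  radius2 <- stats::qchisq(level, df = 2)
  ellipse <- NULL
  if (!degenerate) {
    eig <- eigen(S)
    theta <- seq(0, 2 * pi, length.out = 181)
    circ <- rbind(cos(theta), sin(theta)) * sqrt(radius2)
    path <- t(eig$vectors %*% (sqrt(eig$values) * circ))
    ellipse <- tibble(delta_qalys = path[, 1] + center[["delta_qalys"]],
                      delta_cost = path[, 2] + center[["delta_cost"]])
  }
  quadrants <- tibble(
    quadrant = c("NE", "SE", "SW", "NW"),
    share = c(mean(pts$delta_qalys >= 0 & pts$delta_cost >= 0),
              mean(pts$delta_qalys >= 0 & pts$delta_cost < 0),
              mean(pts$delta_qalys < 0 & pts$delta_cost < 0),
              mean(pts$delta_qalys < 0 & pts$delta_cost >= 0))
  )
  structure(list(points = pts, center = center, cov = S, radius2 = radius2,
                 ellipse = ellipse, quadrants = quadrants, level = level,
                 strategy = strategy, ref = ref, degenerate = degenerate),
            class = "ce_plane")
}

#' @export
autoplot.ce_plane <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$delta_qalys,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (USD)",
                  title = paste(object$strategy, "vs", object$ref))
  if (!object$degenerate) {
    p <- p + ggplot2::geom_path(data = object$ellipse, colour = "red")
  }
  p
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-computes the ICER of a strategy comparison at the low and high end
#' of every registry parameter's plausible range, holding everything else
#' at base case.  Grouped stage-distribution parameters are handled by
#' perturbing one component by +/-20% and renormalizing the others
#' proportionally.
#'
#' @param params Base `ecscreen_params`.
#' @param comparison Character vector of two strategies `c(a, b)`; the
#'   ICER is `icer(a, b)`.
#' @param band Starting age band.
#' @param parameters Optional character vector of registry ids to restrict
#'   the analysis to.
#' @return A `tornado_df` tibble sorted by decreasing span: `parameter`,
#'   `low`, `high` (parameter values), `icer_low`, `icer_high`, `span`.
#'   Attribute `base_icer` carries the base-case ICER.
#' @export
one_way_sa <- function(params, comparison = c("SCR_FOL", "NON_SCR"),
                       band = "40-44", parameters = NULL) {
  stopifnot(length(comparison) == 2, all(comparison %in% strategies()))
  eval_icer <- function(p) {
    a <- accumulate_outcomes(run_cohort(p, comparison[1], band), p)
    b <- accumulate_outcomes(run_cohort(p, comparison[2], band), p)
    icer(a, b)
  }
  base_icer <- eval_icer(params)

  registry <- purrr::keep(parameter_registry(params), ~ .x$one_way)
  if (!is.null(parameters)) {
    registry <- purrr::keep(registry, ~ .x$id %in% parameters)
  }
  rows <- purrr::map_dfr(registry, function(e) {
    rng <- e$range %||% (e$mean * c(0.8, 1.2))
    tibble(parameter = e$id, low = rng[1], high = rng[2],
           icer_low = eval_icer(e$setter(params, rng[1])),
           icer_high = eval_icer(e$setter(params, rng[2])))
  })

  # stage-distribution components: perturb one, renormalize the rest
  for (scenario in c("nonscreening", "screening")) {
    base_sd <- params$stage[[scenario]]
    for (comp in names(base_sd)) {
      id <- paste0("stage_", scenario, "_", comp)
      if (!is.null(parameters) && !id %in% parameters) next
      vals <- purrr::map_dbl(c(0.8, 1.2), function(f) {
        p2 <- params
        v <- base_sd
        v[comp] <- min(v[comp] * f, 1)
        rest <- setdiff(names(v), comp)
        if (sum(base_sd[rest]) > 0) {
          v[rest] <- base_sd[rest] * (1 - v[comp]) / sum(base_sd[rest])
        }
        p2$stage[[scenario]] <- v
        eval_icer(p2)
      })
      rows <- dplyr::bind_rows(rows, tibble(
        parameter = paste0("stage_", scenario, "_", comp),
        low = base_sd[[comp]] * 0.8, high = min(base_sd[[comp]] * 1.2, 1),
        icer_low = vals[1], icer_high = vals[2]))
    }
  }

  if (!is.null(parameters)) {
    rows <- rows[rows$parameter %in% parameters, ]
  }
  rows$span <- abs(rows$icer_high - rows$icer_low)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$span))
  structure(rows, class = c("tornado_df", class(rows)),
            base_icer = base_icer, comparison = comparison, band = band)
}

#' @export
autoplot.tornado_df <- function(object, n = 15, ...) {
  df <- utils::head(object, n)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = paste("Tornado:",
                                paste(attr(object, "comparison"),
                                      collapse = " vs ")))
}
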