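test_that("distribution fits reproduce moments and handle edge cases", {
  f <- fit_distribution(0.852, sd = 0.029, family = "beta")
  expect_equal(f$params$shape1, 126.89, tolerance = 1e-4)
  expect_equal(f$params$shape2, 22.04, tolerance = 1e-3)
  with(f$params, expect_equal(shape1 / (shape1 + shape2), 0.852,
                              tolerance = 1e-9))

  g <- fit_distribution(25217.4, range = 25217.4 * c(0.7, 1.3),
                        family = "gamma")
  with(g$params, expect_equal(shape / rate, 25217.4, tolerance = 1e-6))

  tri <- fit_distribution(0.05, range = c(0, 0.08), family = "triangular")
  expect_equal(tri$params$mode, 0.05)
  expect_error(fit_distribution(0.1, range = c(0.2, 0.3),
                                family = "triangular"), "inside")

  ln <- fit_distribution(0.70, range = c(0.56, 0.84), family = "lognormal")
  expect_equal(exp(ln$params$meanlog), 0.70)  # median at the point estimate

  # a zero SD collapses to a constant sampler
  d <- fit_distribution(0.941, sd = 0, family = "beta")
  expect_equal(sample_dist(d, 5), rep(0.941, 5))

  # infeasible moments are refused
  expect_error(fit_distribution(0.99, sd = 0.4, family = "beta"),
               "infeasible")

  dir <- fit_distribution(c(a = 0.5, b = 0.5), family = "dirichlet",
                          ess = 10)
  expect_equal(unname(dir$params$alpha), c(5, 5))
  expect_error(fit_distribution(c(0.5, 0.6), family = "dirichlet"),
               "simplex")
})

test_that("parameter draws are reproducible, valid and on-simplex", {
  d1 <- sample_parameters(bc, rng_seed = 11)
  d2 <- sample_parameters(bc, rng_seed = 11)
  expect_identical(d1, d2)
  expect_s3_class(validate_parameters(d1), "ecscreen_params")

  # Dirichlet stage draws stay on the simplex exactly
  expect_equal(sum(d1$stage$screening), 1, tolerance = 1e-12)
  expect_equal(sum(d1$stage$nonscreening), 1, tolerance = 1e-12)
  splits <- vapply(c("sm", "mod", "adv"), function(k) {
    as.numeric(d1$scalars$ic_progress_split[[k]]$value)
  }, 1)
  expect_equal(sum(splits), 1, tolerance = 1e-12)

  # an empty registry reproduces the base case unchanged
  expect_equal(sample_parameters(bc, registry = list(), rng_seed = 1),
               validate_parameters(bc))
})

test_that("sampled parameters recover their base-case values in the mean", {
  set.seed(101)
  n <- 10000
  reg <- parameter_registry(bc)
  for (e in reg) {
    spec <- ecscreen:::registry_spec(e, bc$rate_scale)
    draws <- sample_dist(spec, n)
    if (e$family == "dirichlet") {
      for (j in seq_along(e$mean)) {
        if (e$mean[j] == 0) next
        se <- stats::sd(draws[, j]) / sqrt(n)
        expect_lt(abs(mean(draws[, j]) - e$mean[j]), 3 * se + 1e-12)
      }
    } else if (e$family == "lognormal") {
      # parameterized so the median sits at the point estimate
      expect_lt(abs(stats::median(draws) - e$mean),
                5 * stats::sd(draws) / sqrt(n))
    } else if (e$family == "triangular") {
      expect_true(all(draws >= e$range[1] & draws <= e$range[2]))
      expect_lt(abs(mean(draws) - sum(c(e$range, e$mean)) / 3),
                4 * stats::sd(draws) / sqrt(n))
    } else {
      scale <- if (e$family == "rate_beta") bc$rate_scale else 1
      if (!is.null(e$sd) && e$sd == 0) next
      se <- stats::sd(draws) / sqrt(n)
      expect_lt(abs(mean(draws) * scale - e$mean), 3 * se * scale + 1e-12)
    }
  }
})

test_that("small PSA runs are deterministic and acceptability favours follow-up", {
  psa1 <- run_psa(bc, n_iter = 8, seed = 5)
  psa2 <- run_psa(bc, n_iter = 8, seed = 5)
  expect_identical(psa1$draws, psa2$draws)
  expect_equal(nrow(psa1$draws), 8 * 3)
  expect_equal(psa1$failed, 0)

  cc <- ceac(psa1, c(0, 25000, 51000, 102000))
  sums <- dplyr::summarise(dplyr::group_by(cc, wtp),
                           s = sum(probability))
  expect_equal(sums$s, rep(1, 4), tolerance = 1e-12)
  # at the published willingness-to-pay, follow-up screening dominates
  at_wtp <- cc[cc$wtp == 51000, ]
  expect_equal(at_wtp$strategy[which.max(at_wtp$probability)], "SCR_FOL")
})

test_that("CEAC matches manual net-monetary-benefit ranking on a toy set", {
  draws <- tibble::tibble(
    iteration = rep(1:3, each = 2),
    strategy = rep(c("A", "B"), 3),
    cost = c(100, 150, 100, 90, 100, 100),
    qalys = c(10, 11, 10, 9, 10, 10))
  toy <- structure(list(draws = draws, n_iter = 3, seed = 1, band = "40-44",
                        cohort_size = 1, wtp = 51000, failed = 0L),
                   class = "psa_result")
  # wtp 100: NMB A = 900 each iter; B = 950, 810, 900 -> B, A, tie
  cc <- ceac(toy, 100)
  expect_equal(cc$probability[cc$strategy == "A"], (0 + 1 + 0.5) / 3)
  expect_equal(cc$probability[cc$strategy == "B"], (1 + 0 + 0.5) / 3)
  # wtp 0 reduces to least cost
  cc0 <- ceac(toy, 0)
  expect_equal(cc0$probability[cc0$strategy == "A"], (1 + 0 + 0.5) / 3)

  # single strategy: curve is identically one
  one <- structure(list(draws = draws[draws$strategy == "A", ],
                        n_iter = 3, seed = 1, band = "40-44",
                        cohort_size = 1, wtp = 51000, failed = 0L),
                   class = "psa_result")
  cc1 <- ceac(one, c(0, 1, 2))
  expect_equal(cc1$probability, rep(1, 3))
})

test_that("the cheapest strategy's acceptability declines with WTP", {
  set.seed(7)
  n <- 400
  # cheap strategy A, expensive-but-effective B with positive QALY gain
  draws <- tibble::tibble(
    iteration = rep(1:n, each = 2),
    strategy = rep(c("A", "B"), n),
    cost = as.numeric(rbind(rnorm(n, 100, 5), rnorm(n, 160, 5))),
    qalys = as.numeric(rbind(rnorm(n, 10, 0.1), rnorm(n, 11, 0.1))))
  toy <- structure(list(draws = draws, n_iter = n, seed = 7, band = "x",
                        cohort_size = 1, wtp = 60, failed = 0L),
                   class = "psa_result")
  cc <- ceac(toy, seq(0, 200, by = 20))
  pa <- cc$probability[cc$strategy == "A"]
  expect_true(all(diff(pa) <= 1e-12))
})

test_that("confidence ellipses cover as advertised on Gaussian clouds", {
  skip_if_not_installed("MASS")
  set.seed(13)
  n <- 10000
  pts <- MASS::mvrnorm(n, mu = c(0.5, 40), Sigma = diag(c(4, 4)))
  draws <- tibble::tibble(
    iteration = rep(1:n, 2),
    strategy = rep(c("REF", "NEW"), each = n),
    cost = c(rep(0, n), pts[, 2]),
    qalys = c(rep(0, n), pts[, 1]))
  toy <- structure(list(draws = draws, n_iter = n, seed = 1, band = "x",
                        cohort_size = 1, wtp = 51000, failed = 0L),
                   class = "psa_result")
  pl <- ce_plane_ellipse(toy, "NEW", "REF", level = 0.95)
  expect_false(pl$degenerate)
  # isotropic cloud: eigenvalues agree within sampling error
  ev <- eigen(pl$cov)$values
  expect_equal(ev[1] / ev[2], 1, tolerance = 0.1)
  # empirical coverage of the fitted ellipse
  d2 <- stats::mahalanobis(cbind(pl$points$delta_qalys,
                                 pl$points$delta_cost),
                           pl$center[c("delta_qalys", "delta_cost")],
                           pl$cov)
  expect_equal(mean(d2 <= pl$radius2), 0.95, tolerance = 0.015)

  # identical points give the degenerate-ellipse signal
  same <- draws
  same$cost[same$strategy == "NEW"] <- 7
  same$qalys[same$strategy == "NEW"] <- 1
  toy2 <- structure(list(draws = same, n_iter = n, seed = 1, band = "x",
                         cohort_size = 1, wtp = 51000, failed = 0L),
                    class = "psa_result")
  expect_true(ce_plane_ellipse(toy2, "NEW", "REF")$degenerate)
})

test_that("one-way analysis spans behave and the discount bound holds", {
  subset <- c("discount_rate", "rr_screening", "cost_MOD", "util_LGIN")
  tor <- one_way_sa(bc, comparison = c("SCR_FOL", "NON_SCR"),
                    band = "40-44", parameters = subset)
  expect_setequal(tor$parameter, subset)
  expect_true(all(tor$span >= 0))
  expect_equal(tor$span, sort(tor$span, decreasing = TRUE))
  # enumeration order does not change the spans
  tor_rev <- one_way_sa(bc, comparison = c("SCR_FOL", "NON_SCR"),
                        band = "40-44", parameters = rev(subset))
  expect_equal(dplyr::arrange(tibble::as_tibble(tor), parameter),
               dplyr::arrange(tibble::as_tibble(tor_rev), parameter))
  # the discount rate swings the ICER but never past the WTP threshold
  disc <- tor[tor$parameter == "discount_rate", ]
  expect_lt(disc$icer_high, 51000)

  # a zero-valued parameter contributes zero span
  p0 <- bc
  p0$age_rates$ec_incidence_lgin[] <- 0
  tor0 <- one_way_sa(p0, band = "40-44",
                     parameters = "ec_incidence_lgin_40-44")
  expect_equal(tor0$span, 0)
})
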