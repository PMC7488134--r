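test_that("transition rows compose published scalars with background death", {
  r <- build_transition_row("IC", "NON_SCR", 42, bc)
  expect_equal(r[["DFS_IC"]], 0.9363 - 0.0012173)       # = 0.9350827
  expect_equal(r[["SM"]], 0.0534 * 0.2143)              # = 0.0114436
  expect_equal(r[["MOD"]], 0.0534 * 0.5714)             # = 0.0305128
  expect_equal(r[["ADV"]], 0.0534 * 0.2143)
  expect_equal(r[["IC"]], 0.0103, tolerance = 1e-9)     # stay mass
  expect_equal(r[["DEATH"]], 0.0012173)
  expect_equal(sum(r), 1, tolerance = 1e-15)

  d <- build_transition_row("DEATH", "NON_SCR", 42, bc)
  expect_equal(as.numeric(d), c(rep(0, 10), 1))

  n <- build_transition_row("NORMAL", "NON_SCR", 42, bc)
  expect_equal(sum(n[c("IC", "SM", "MOD", "ADV")]), 1.36e-5,
               tolerance = 1e-12)
  expect_equal(unname(n[c("IC", "SM", "MOD", "ADV")] / 1.36e-5),
               unname(bc$stage$nonscreening), tolerance = 1e-9)
  expect_equal(n[["LGIN"]], 0)

  # screened arms deflate the incidence hazard by the RR
  ns <- build_transition_row("NORMAL", "SCR_FOL", 42, bc)
  expect_equal(sum(ns[c("IC", "SM", "MOD", "ADV")]), 1.36e-5 * 0.70,
               tolerance = 1e-12)

  # LGIN regresses to normal only with follow-up, and follow-up detection
  # shifts its incident cases to the screening stage distribution
  lf <- build_transition_row("LGIN", "SCR_FOL", 42, bc)
  ln <- build_transition_row("LGIN", "SCR_NFOL", 42, bc)
  expect_equal(lf[["NORMAL"]], 0.1427)
  expect_equal(ln[["NORMAL"]], 0)
  expect_equal(unname(lf[c("IC", "SM", "MOD", "ADV")] / 4.96e-5),
               unname(bc$stage$screening), tolerance = 1e-9)
  expect_equal(unname(ln[c("IC", "SM", "MOD", "ADV")] / 4.96e-5),
               unname(bc$stage$nonscreening), tolerance = 1e-9)
})

test_that("transition matrices are row-stochastic across all ages and arms", {
  for (s in strategies()) {
    for (age in 42:79) {
      m <- build_transition_matrix(s, age, bc)
      expect_equal(unname(rowSums(m)), rep(1, 11), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m["DEATH", ]), c(rep(0, 10), 1))
    }
  }
})

test_that("strategies differ only where screening acts", {
  m0 <- build_transition_matrix("NON_SCR", 50, bc)
  m1 <- build_transition_matrix("SCR_FOL", 50, bc)
  diff_rows <- health_states()[rowSums(abs(m1 - m0)) > 0]
  expect_setequal(diff_rows, c("NORMAL", "LGIN"))
})

test_that("elderly multipliers raise cancer-state death entries", {
  sc <- bc$scalars
  m66 <- build_transition_matrix("NON_SCR", 66, bc)
  d_nor66 <- background_death_prob(bc$age_rates[6, ])
  expect_equal(m66["SM", "DEATH"], 0.0994 * 1.30 + d_nor66)
  expect_equal(m66["MOD", "DEATH"], 0.2988 * 1.20 + d_nor66)
  expect_equal(m66["PFS_ADV", "DEATH"], 0.4303 * 1.16 + d_nor66)
  m64 <- build_transition_matrix("NON_SCR", 64, bc)
  d_nor64 <- background_death_prob(bc$age_rates[5, ])
  expect_equal(m64["ADV", "DEATH"], 0.4613 + d_nor64)
})

test_that("the cohort iteration equals explicit matrix products", {
  # occupancy after k cycles must equal v0 times the ordered matrix product
  tr <- bc_trace("SCR_FOL", "40-44")
  v0 <- bc$econ$cohort_size * initial_state_vector("SCR_FOL", "40-44", bc)
  prod <- diag(11)
  for (k in 1:5) {
    M <- build_transition_matrix("SCR_FOL", 41 + k, bc)
    prod <- prod %*% unclass(M)
    vk <- as.numeric(v0 %*% prod)
    expect_equal(as.numeric(tr[tr$cycle == k, health_states()]), vk,
                 tolerance = 1e-12)
  }
})

test_that("traces conserve the cohort and absorb into death monotonically", {
  for (s in strategies()) {
    for (b in start_bands(bc)) {
      tr <- bc_trace(s, b)
      occ <- as.matrix(tibble::as_tibble(tr)[, health_states()])
      expect_equal(unname(rowSums(occ)),
                   rep(bc$econ$cohort_size, nrow(occ)), tolerance = 1e-6)
      expect_true(all(diff(occ[, "DEATH"]) >= 0))
      expect_true(all(tr$new_ec_cases >= 0))
      expect_true(all(tr$ec_deaths >= 0))
      # cancer-attributed deaths never exceed total deaths in a cycle
      expect_true(all(tr$ec_deaths[-1] <= diff(occ[, "DEATH"]) + 1e-9))
    }
  }
})

test_that("the horizon follows the attained-age convention", {
  expect_equal(max(bc_trace("NON_SCR", "40-44")$cycle), 38)  # ages 42..79
  expect_equal(max(bc_trace("NON_SCR", "65-69")$cycle), 13)  # ages 67..79
  tr_low <- run_cohort(bc, "NON_SCR", "65-69",
                       attained_age_convention = "lower")
  expect_equal(max(tr_low$cycle), 15)                        # ages 65..79
  expect_error(run_cohort(bc, "SCR_FOL", "70-74"), "screened band")
})

test_that("degenerate parameter sets produce the expected limiting traces", {
  # no incidence, no detection: nobody ever enters a cancer state
  p0 <- bc
  p0$age_rates$ec_incidence[] <- 0
  p0$age_rates$ec_incidence_lgin[] <- 0
  p0$age_rates$ec_detection[1:6] <- 0
  p0$age_rates$lgin_detection[1:6] <- 0
  tr0 <- run_cohort(p0, "SCR_FOL", "40-44")
  expect_equal(cumulative_ec_incidence(tr0), 0)
  expect_equal(cumulative_ec_mortality(tr0), 0)
  expect_true(all(as.matrix(tr0[, c("IC", "SM", "MOD", "ADV")]) == 0))

  # with baseline counting on, cumulative incidence includes detected
  # prevalence and nothing else when incidence is zero
  p1 <- p0
  p1$age_rates$ec_detection[1] <- 100
  tr1 <- run_cohort(p1, "SCR_FOL", "40-44", include_baseline_cases = TRUE)
  expect_equal(cumulative_ec_incidence(tr1), 100)

  # doubling incidence raises cumulative incidence
  p2 <- bc
  p2$age_rates$ec_incidence <- p2$age_rates$ec_incidence * 2
  expect_gt(cumulative_ec_incidence(run_cohort(p2, "NON_SCR", "40-44")),
            cumulative_ec_incidence(bc_trace("NON_SCR", "40-44")))
})

test_that("screening reduces cumulative incidence in every starting band", {
  for (b in start_bands(bc)) {
    ci_non <- cumulative_ec_incidence(bc_trace("NON_SCR", b))
    ci_fol <- cumulative_ec_incidence(bc_trace("SCR_FOL", b))
    ci_nfol <- cumulative_ec_incidence(bc_trace("SCR_NFOL", b))
    expect_lt(ci_fol, ci_non)
    expect_lt(ci_nfol, ci_non)
    expect_lt(ci_fol, ci_nfol)  # follow-up averts LGIN progression too
  }
})
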