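test_that("the packaged base case carries every printed input exactly", {
  expect_equal(bc$econ$discount_rate, 0.05)
  expect_equal(bc$econ$inflation_rate, 0.047)
  expect_equal(bc$econ$wtp, 51000)
  expect_equal(bc$econ$cohort_size, 1e5)
  expect_equal(bc$econ$horizon_age, 79)

  ar <- bc$age_rates
  expect_equal(ar$band,
               c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69",
                 "70-74", "75-79"))
  expect_equal(ar$ec_incidence,
               c(1.36, 4.90, 9.93, 25.41, 35.48, 46.25, 63.97, 64.45))
  expect_equal(ar$ec_incidence_lgin,
               c(4.96, 17.68, 34.95, 84.00, 108.02, 118.02, 163.22, 164.36))
  expect_equal(ar$ec_detection[1:6],
               c(16.92, 70.65, 193.45, 518.59, 976.17, 2072.48))
  expect_true(all(is.na(ar$ec_detection[7:8])))
  expect_equal(ar$lgin_detection[1:6],
               c(130.56, 545.00, 1492.33, 4000.54, 7530.48, 15987.72))
  expect_equal(ar$ec_mortality,
               c(0.68, 2.19, 7.57, 14.87, 22.03, 33.08, 53.42, 65.73))
  expect_equal(ar$all_cause_mortality,
               c(122.41, 184.60, 343.55, 475.18, 738.42, 1262.28,
                 2380.26, 4094.67))

  expect_equal(unname(bc$stage$nonscreening),
               c(0.0365, 0.0493, 0.6606, 0.2536))
  expect_equal(unname(bc$stage$screening),
               c(0.8824, 0.0252, 0.0672, 0.0252))

  expect_equal(bc$costs$screening[["NORMAL"]], 60.3)
  expect_equal(bc$costs$screening[["DFS_IC"]], 0)
  expect_equal(unname(bc$costs$treatment[c("LGIN", "IC", "SM", "MOD", "ADV",
                                           "DFS_IC", "DFS_SM", "DFS_MOD",
                                           "PFS_ADV")]),
               c(149.5, 17561.9, 20781.6, 25217.4, 23702.5,
                 837.5, 1580.0, 1580.0, 2873.0))
  expect_equal(bc$costs$sa_fraction, 0.30)

  u <- tibble::deframe(bc$utilities[, c("state", "mean")])
  expect_equal(unname(u[health_states()]),
               c(1.000, 0.941, 0.852, 0.693, 0.780, 0.720,
                 0.940, 0.870, 0.810, 0.740, 0.000))
  sd <- tibble::deframe(bc$utilities[, c("state", "sd")])
  expect_equal(unname(sd[c("LGIN", "IC", "SM", "ADV")]),
               c(0.089, 0.029, 0.310, 0.180))

  sc <- bc$scalars
  val <- function(k) as.numeric(sc[[k]]$value)
  expect_equal(val("lgin_to_normal"), 0.1427)
  expect_equal(val("ic_to_dfs_gross"), 0.9363)
  expect_equal(val("ic_progress"), 0.0534)
  expect_equal(as.numeric(sc$ic_progress_split$sm$value), 0.2143)
  expect_equal(as.numeric(sc$ic_progress_split$mod$value), 0.5714)
  expect_equal(val("dfs_ic_to_ic"), 0.0069)
  expect_equal(val("dfs_ic_progress"), 0.0268)
  expect_equal(as.numeric(sc$dfs_ic_progress_split$sm$value), 0.5556)
  expect_equal(val("sm_to_dfs_gross"), 0.9051)
  expect_equal(val("sm_progress"), 0.1386)
  expect_equal(as.numeric(sc$sm_progress_split$mod$value), 0.7562)
  expect_equal(val("dfs_sm_to_sm"), 0.0393)
  expect_equal(val("dfs_sm_progress"), 0.0883)
  expect_equal(val("mod_to_dfs_gross"), 0.5930)
  expect_equal(val("mod_to_adv"), 0.0317)
  expect_equal(val("dfs_mod_to_mod"), 0.0425)
  expect_equal(val("dfs_mod_to_adv"), 0.0097)
  expect_equal(val("adv_to_pfs_gross"), 0.1967)
  expect_equal(val("pfs_progress"), 0.7002)
  expect_equal(val("rr_screening"), 0.70)
  expect_equal(val("lgin_ec_risk_ratio"), 3.66)
  ecd <- vapply(c("sm", "dfs_sm", "mod", "dfs_mod", "adv", "pfs"),
                function(k) as.numeric(sc$ec_death[[k]]$value), 1)
  expect_equal(unname(ecd),
               c(0.0994, 0.0633, 0.2988, 0.1902, 0.4613, 0.4303))
  mult <- vapply(c("sm", "mod", "adv"),
                 function(k) as.numeric(sc$elderly_death_rr[[k]]$value), 1)
  expect_equal(unname(mult), c(1.30, 1.20, 1.16))
})

test_that("state space and stage-class predicates are as modelled", {
  expect_length(health_states(), 11)
  expect_length(strategies(), 3)
  expect_true(all(is_early_ec(c("IC", "SM"))))
  expect_true(all(is_invasive_ec(c("MOD", "ADV"))))
  expect_false(any(is_early_ec(c("MOD", "ADV", "NORMAL", "DFS_IC"))))
  expect_false(any(is_invasive_ec(c("IC", "SM", "LGIN"))))
  expect_error(is_early_ec("MODERATE"))
})

test_that("the loader rejects malformed files with informative errors", {
  path <- system.file("extdata", "base_case.yaml", package = "ecscreen")
  raw <- yaml::read_yaml(path)

  reload <- function(x) {
    f <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    yaml::write_yaml(x, f)
    load_parameters(f)
  }

  bad <- raw; bad$mystery_block <- list(a = 1)
  expect_error(reload(bad), "unknown top-level")

  bad <- raw; bad$economics$discount_rate <- NULL
  expect_error(reload(bad), "economics")

  bad <- raw; bad$age_rates[[1]]$ec_incidence <- NULL
  expect_error(reload(bad), "ec_incidence")

  bad <- raw; bad$age_rates[[1]]$typo_field <- 3
  expect_error(reload(bad), "typo_field")

  # stage proportions summing to 0.5 violate the simplex
  bad <- raw
  bad$stage_distribution$nonscreening <-
    list(ic = 0.1, sm = 0.1, mod = 0.2, adv = 0.1)
  expect_error(reload(bad), "sum")

  expect_error(load_parameters(file.path(tempdir(), "nope.yaml")),
               "not found")
})

test_that("single-field corruptions of the fixture are caught by validation", {
  corrupt <- function(mutator, pattern) {
    p <- bc
    p <- mutator(p)
    expect_error(validate_parameters(p), pattern)
  }
  corrupt(function(p) { p$costs$treatment[["DEATH"]] <- 5; p }, "DEATH")
  corrupt(function(p) { p$costs$treatment[["NORMAL"]] <- 10; p }, "NORMAL")
  corrupt(function(p) { p$costs$treatment[["MOD"]] <- -1; p }, "negative")
  corrupt(function(p) {
    p$utilities$mean[p$utilities$state == "SM"] <- 1.2; p
  }, "utility")
  corrupt(function(p) {
    p$age_rates$ec_mortality[8] <- 5000; p
  }, "mortality")
  corrupt(function(p) { p$scalars$sm_progress$value <- 1.5; p }, "0, 1")
  corrupt(function(p) { p$scalars$ic_progress_split$sm$value <- 0.9; p },
          "simplex")
  corrupt(function(p) { p$scalars$elderly_death_rr$mod$value <- 0.8; p },
          ">= 1")
  corrupt(function(p) { p$stage$screening[1] <- 0.5; p }, "sum")
})

test_that("parameter sets round-trip losslessly through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(bc, f)
  back <- load_parameters(f)
  expect_equal(back$age_rates, bc$age_rates)
  expect_equal(back$utilities, bc$utilities)
  expect_equal(back$costs, bc$costs)
  expect_equal(back$stage$nonscreening, bc$stage$nonscreening)
  expect_equal(back$stage$screening, bc$stage$screening)
  expect_equal(back$econ, bc$econ)
  # scalar values survive exactly
  for (k in c("lgin_to_normal", "rr_screening", "pfs_progress")) {
    expect_identical(as.numeric(back$scalars[[k]]$value),
                     as.numeric(bc$scalars[[k]]$value))
  }
})
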