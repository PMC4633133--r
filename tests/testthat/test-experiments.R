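test_that("the catalog contains the expected paradigms and designs", {
  cat_ <- experiment_catalog()
  expect_setequal(names(cat_),
                  c("latent_inhibition", "overshadowing", "forward_blocking",
                    "overexpectation", "conditioned_inhibition",
                    "overshadowing_second_order", "second_order_extinction",
                    "serial_compound_extinction", "serial_latent_inhibition",
                    "serial_recovery_from_overshadowing"))

  fb <- cat_[["forward_blocking"]]$conditions
  expect_equal(format_design(parse_design(fb[["blocking"]])),
               "A→+; AB→+; B→?")
  expect_equal(format_design(parse_design(fb[["unblocking"]])),
               "A→+; AB→+; A→-; B→?")

  oe1 <- parse_design(cat_[["overexpectation"]]$conditions[[1]])$phases[[1]]
  expect_equal(vapply(oe1$trial_types, `[[`, character(1), "label"),
               c("A→+", "B→+"))

  sce <- cat_[["serial_compound_extinction"]]
  probes <- parse_design(sce$conditions[["extinction"]])$test_trials
  expect_equal(probes[[1]]$events, list("Z"))
  expect_true(all(vapply(cat_, `[[`, integer(1), "n_trials") == 10L))
})

test_that("probe responses are finite and read out without updating weights", {
  res <- run_experiment("latent_inhibition")
  expect_true(all(is.finite(res$responses$value)))
  run <- res$runs[["no_pre"]][["KF"]]
  # final trained weight is unchanged by reading out the probe
  expect_equal(unname(run$responses["A"]), unname(run$state$w["A"]))
  expect_equal(nrow(run$trace$steps), 10L)  # probes add no learning steps
})

test_that("pre-exposure retards Kalman filter conditioning but not RW", {
  p <- model_params()
  res <- run_experiment("latent_inhibition", params = p)
  rep_ <- ordering_report(res)
  expect_true(all(rep_$pass))

  # the point-estimate model learns nothing from unreinforced pre-exposure
  pre <- run_model("A→-; A→+; A→?", "RW", p)$responses
  no_pre <- run_model("A→+; A→?", "RW", p)$responses
  expect_identical(pre, no_pre)
})

test_that("ordering_report tabulates one row per constraint with margins", {
  res <- run_experiment("forward_blocking")
  rep_ <- ordering_report(res)
  expect_equal(nrow(rep_), 1L)
  expect_named(rep_, c("model", "description", "lhs", "rhs", "margin",
                       "pass"))
  expect_equal(rep_$margin, rep_$lhs - rep_$rhs)
  expect_true(rep_$pass)

  # conditioned inhibition: recovery toward zero from below
  ci <- run_experiment("conditioned_inhibition")
  expect_true(all(ordering_report(ci)$pass))
  expect_true(all(ci$responses$value <= 0))
})

test_that("TD/KTD contrast experiments separate only the Bayesian model", {
  for (nm in c("overshadowing_second_order", "second_order_extinction",
               "serial_compound_extinction", "serial_latent_inhibition",
               "serial_recovery_from_overshadowing")) {
    rep_ <- ordering_report(run_experiment(nm))
    expect_true(all(rep_$pass), label = nm)
  }
})

test_that("both real-time models acquire second-order value", {
  p <- model_params()
  ktd <- run_model("A→+; Z→A; Z→?", "KTD", p)$responses["Z"]
  td <- run_model("A→+; Z→A; Z→?", "TD", p)$responses["Z"]
  expect_gt(ktd, 0)
  expect_gt(td, 0)
})

test_that("serial figure orderings are stable across bins and tau2", {
  serial <- c("second_order_extinction", "serial_compound_extinction",
              "serial_latent_inhibition", "serial_recovery_from_overshadowing",
              "overshadowing_second_order")
  for (bins in c(2L, 4L)) {
    for (tau2 in c(0.005, 0.01, 0.015)) {
      p <- model_params(bins_per_stimulus = bins, tau2 = tau2)
      for (nm in serial) {
        rep_ <- ordering_report(run_experiment(nm, params = p))
        expect_true(all(rep_$pass),
                    label = sprintf("%s bins=%d tau2=%g", nm, bins, tau2))
      }
    }
  }
})

test_that("experiment runs are deterministic", {
  a <- run_experiment("serial_compound_extinction", seed = 3L)
  b <- run_experiment("serial_compound_extinction", seed = 3L)
  expect_identical(a$responses, b$responses)
  expect_identical(a$runs[["extinction"]][["KTD"]]$trace$w,
                   b$runs[["extinction"]][["KTD"]]$trace$w)

  s1 <- run_model("A→+ / B→-", "KF", schedule = "shuffled", seed = 11L)
  s2 <- run_model("A→+ / B→-", "KF", schedule = "shuffled", seed = 11L)
  expect_identical(s1$trace$w, s2$trace$w)
})

test_that("model/design compatibility is enforced", {
  expect_error(run_model("Z→X→+", "KF"), "serial")
  expect_error(run_model("Z→X→+", "RW"), "serial")
  expect_silent(run_model("Z→X→+", "KTD"))
})

test_that("a design with no training trials yields zero weights and responses", {
  run <- run_model("B→?", "KF")
  expect_equal(unname(run$state$w), 0)
  expect_equal(unname(run$responses["B"]), 0)
  expect_equal(nrow(run$trace$steps), 0L)
  expect_equal(nrow(trace_table(run)), 0L)
})
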