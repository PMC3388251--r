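test_that("two tail constraints are reproduced exactly by the solved
           log-normal", {
  par <- calibrate_unaffected_irt(tail_constraint(50, 0.0243),
                                  tail_constraint(60, 0.0103))
  # verify against the numeric CDF, not against the solver's own algebra
  expect_lt(abs(plnorm(50, par[["mu"]], par[["sigma"]],
                       lower.tail = FALSE) - 0.0243), 1e-10)
  expect_lt(abs(plnorm(60, par[["mu"]], par[["sigma"]],
                       lower.tail = FALSE) - 0.0103), 1e-10)
  # constraint order must not matter
  par_rev <- calibrate_unaffected_irt(tail_constraint(60, 0.0103),
                                      tail_constraint(50, 0.0243))
  expect_equal(par, par_rev)
})

test_that("unit-spaced standard-normal quantiles give sigma exactly 1", {
  # thresholds a factor e apart with exceedance probs whose z-scores differ
  # by exactly 1: sigma = log(t2/t1) / 1 = 1
  p1 <- 1 - pnorm(1)
  p2 <- 1 - pnorm(2)
  par <- calibrate_unaffected_irt(tail_constraint(50, p1),
                                  tail_constraint(50 * exp(1), p2))
  expect_equal(par[["sigma"]], 1, tolerance = 1e-12)
})

test_that("non-monotone tail constraints are rejected", {
  expect_error(
    calibrate_unaffected_irt(tail_constraint(50, 0.0103),
                             tail_constraint(60, 0.0243)),
    "inconsistent"
  )
  expect_error(
    calibrate_unaffected_irt(tail_constraint(50, 0.01),
                             tail_constraint(50, 0.02)),
    "distinct"
  )
  expect_error(tail_constraint(50, 0), "strictly in")
  expect_error(tail_constraint(-1, 0.5), NA_character_, class = "error")
})

test_that("sampled unaffected IRT reproduces the calibrated tails", {
  model <- default_biomarker_model()
  set.seed(42)
  n <- 4e5
  irt <- sample_biomarkers("UNAFFECTED", model, n)$irt_ugl
  for (tc in list(c(50, 0.0243), c(60, 0.0103))) {
    p_hat <- mean(irt >= tc[1])
    se <- sqrt(tc[2] * (1 - tc[2]) / n)
    expect_lt(abs(p_hat - tc[2]), 4 * se)
  }
})

test_that("analytic tails agree with the calibration constraints", {
  model <- default_biomarker_model()
  expect_equal(marker_tail_probability(model, 50), 0.0243, tolerance = 1e-10)
  expect_equal(marker_tail_probability(model, 60), 0.0103, tolerance = 1e-10)
})

test_that("degenerate sigma = 0 yields a point mass and sampling stays
           positive and finite", {
  params <- expand.grid(class = c("UNAFFECTED", "CARRIER", "CLASSICAL_CF",
                                  "NON_CLASSICAL_CF"),
                        marker = c("IRT", "PAP"), stringsAsFactors = FALSE)
  params$mu <- log(20)
  params$sigma <- 0
  model <- biomarker_model(params)
  draws <- sample_biomarkers("CARRIER", model, 100)
  expect_true(all(draws$irt_ugl == exp(log(20))))
  expect_true(all(draws$pap_ugl == exp(log(20))))
  expect_equal(unique(draws$irt_ugl), 20)

  set.seed(7)
  d2 <- sample_biomarkers("CLASSICAL_CF", default_biomarker_model(), 5000)
  expect_true(all(is.finite(d2$irt_ugl) & d2$irt_ugl > 0))
  expect_true(all(is.finite(d2$pap_ugl) & d2$pap_ugl > 0))
})

test_that("class IRT distributions are stochastically ordered over the
           working quantile range", {
  model <- default_biomarker_model()
  p <- seq(0.001, 0.999, length.out = 200)
  q_of <- function(class) {
    pr <- model$params
    row <- pr[pr$class == class & pr$marker == "IRT", ]
    qlnorm(p, row$mu, row$sigma)
  }
  expect_true(all(q_of("CLASSICAL_CF") > q_of("CARRIER")))
  expect_true(all(q_of("CARRIER") > q_of("UNAFFECTED")))
  # PAP: CF classes dominate the unaffected distribution
  q_pap <- function(class) {
    pr <- model$params
    row <- pr[pr$class == class & pr$marker == "PAP", ]
    qlnorm(p, row$mu, row$sigma)
  }
  expect_true(all(q_pap("CLASSICAL_CF") > q_pap("UNAFFECTED")))
})

test_that("raising a class's location raises its screen-positive rate", {
  model <- default_biomarker_model()
  shifted <- model$params
  sel <- shifted$class == "NON_CLASSICAL_CF" & shifted$marker == "IRT"
  shifted$mu[sel] <- shifted$mu[sel] + 0.3
  model_hi <- biomarker_model(shifted)
  cfg <- protocol_config()
  rate <- function(m) {
    set.seed(99)
    bm <- sample_biomarkers("NON_CLASSICAL_CF", m, 20000)
    co <- make_newborn(bm$irt_ugl, bm$pap_ugl, "PANEL_MUTATION",
                       "PANEL_MUTATION", id = seq_len(nrow(bm)),
                       phenotype = "NON_CLASSICAL_CF")
    mean(screen_cohort(co, cfg)$outcome == "CF_REFERRAL")
  }
  expect_gte(rate(model_hi), rate(model))
})

test_that("uncalibrated or incomplete models are refused", {
  expect_error(sample_biomarkers("UNAFFECTED", list(calibrated = FALSE)),
               "not calibrated")
  bad <- default_biomarker_model()$params[-1, ]
  expect_error(biomarker_model(bad), "missing")
})

test_that("log-scale correlation induces the requested dependence", {
  model <- default_biomarker_model(rho = 0.8)
  set.seed(5)
  d <- sample_biomarkers("UNAFFECTED", model, 20000)
  r <- cor(log(d$irt_ugl), log(d$pap_ugl))
  expect_gt(r, 0.75)
  expect_lt(r, 0.85)
})
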