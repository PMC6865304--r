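test_that("person-time expansion follows the interval arithmetic", {
  rows <- expand_person_time(toy_cohort(), interval_width = 1)
  # treated at 10.5 weeks -> 11 rows, final exposure 0.5, event on last row
  r1 <- rows[rows$id == 1, ]
  expect_equal(nrow(r1), 11)
  expect_equal(r1$exposure[11], 0.5)
  expect_equal(r1$event, c(rep(0L, 10), 1L))
  # censored at 3.0 weeks -> 3 rows, no event
  r2 <- rows[rows$id == 2, ]
  expect_equal(nrow(r2), 3)
  expect_true(all(r2$event == 0L))
  # exposure conservation
  expect_equal(sum(rows$exposure), sum(toy_cohort()$time_weeks))
  # midpoint evaluation
  expect_equal(r1$t_eval[1], 0.5)
  expect_equal(r1$t_eval[11], 10.25)
})

test_that("non-positive follow-up rows are rejected with their ids", {
  co <- toy_cohort()
  co$time_weeks[2] <- 0
  expect_warning(rows <- expand_person_time(co), "id 2")
  expect_false(2 %in% rows$id)
})

test_that("intercept-only fit recovers the occurrence/exposure rate", {
  co <- simulate_cohort(n = 800, seed = 5)
  rows <- expand_person_time(co)
  f <- fit_person_time(rows, terms = "intercept")
  expect_equal(unname(exp(f$coef)), sum(rows$event) / sum(rows$exposure),
               tolerance = 1e-8)
})

test_that("two-stratum fit recovers closed-form stratified rates", {
  # saturated log-linear model in the sex code: fitted rates must equal the
  # per-stratum events/exposure exactly
  co <- simulate_cohort(n = 1000, seed = 6)
  rows <- expand_person_time(co)
  f <- fit_person_time(rows, terms = c("intercept", "sex"))
  for (s in 1:2) {
    i <- rows$sex == s
    expect_equal(unname(exp(f$coef[1] + f$coef[2] * s)),
                 sum(rows$event[i]) / sum(rows$exposure[i]), tolerance = 1e-7)
  }
})

test_that("fitted rates are invariant to interval refinement under constant hazard", {
  m0 <- digirop_model()
  m0$estimates[] <- 0
  m0$estimates["intercept"] <- log(0.01)
  co <- simulate_cohort(n = 500, model = m0, seed = 7)
  r1 <- fit_person_time(expand_person_time(co, 1), terms = "intercept")
  r2 <- fit_person_time(expand_person_time(co, 0.5), terms = "intercept")
  expect_equal(unname(r1$coef), unname(r2$coef), tolerance = 1e-8)
})

test_that("information-matrix covariance matches the numerical Hessian", {
  co <- simulate_cohort(n = 1500, seed = 8)
  rows <- expand_person_time(co)
  fit <- fit_person_time(rows)
  X <- design_row(rows[, c("ga_weeks", "sex", "bwsds")], rows$t_eval)
  off <- log(rows$exposure)
  ll <- function(b) {
    eta <- drop(X %*% b) + off
    sum(rows$event * eta - exp(eta))
  }
  b0 <- unname(coef(fit))
  h <- 1e-5 * pmax(abs(b0), 1)
  H <- matrix(0, 14, 14)
  for (i in 1:14) for (j in i:14) {
    ei <- ej <- rep(0, 14); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (ll(b0 + ei + ej) - ll(b0 + ei - ej) - ll(b0 - ei + ej) +
         ll(b0 - ei - ej)) / (4 * h[i] * h[j])
  }
  Vnum <- solve(-H)
  V <- unname(vcov(fit))
  expect_lt(max(abs(V - Vnum)) / max(abs(V)), 1e-4)
})

test_that("estimates recover the generating coefficients on one large cohort", {
  truth <- coef(digirop_model())
  co <- simulate_cohort(n = 5000, seed = 9)
  fit <- digirop_fit(co)
  within3 <- abs(coef(fit) - truth) <= 3 * fit$ses
  expect_gte(sum(within3), 13)
})

test_that("Wald hazard ratios follow the contrast arithmetic", {
  m <- digirop_model()
  z <- wald_hr(m, rep(0, 14))
  expect_equal(z$hr, 1)
  expect_equal(c(z$lower, z$upper), c(1, 1))
  cc <- rep(0, 14); cc[3] <- 1   # the 8-12 week slope
  w <- wald_hr(m, cc)
  expect_equal(w$hr, exp(0.3618))
  # CI symmetric on the log scale
  expect_equal(log(w$upper) - log(w$hr), log(w$hr) - log(w$lower))
  expect_error(wald_hr(m, rep(0, 13)), "length 14")
})

test_that("interaction screening keeps strong effects and returns base with no candidates", {
  rows <- expand_person_time(simulate_cohort(n = 400, seed = 10))
  out <- interaction_screen(rows, candidates = list())
  expect_identical(out$terms, digirop_term_names()[1:9])
  expect_length(out$retained, 0)

  # amplify the sex-by-GA interaction far beyond its SE and screen
  m_strong <- digirop_model()
  m_strong$estimates["sex_x_ga"] <- -0.8
  co <- simulate_cohort(n = 4000, model = m_strong, seed = 11)
  rows <- expand_person_time(co)
  out <- interaction_screen(rows,
                            candidates = list(sex_x_ga = "sex_x_ga"))
  expect_true("sex_x_ga" %in% out$retained)
  expect_lt(out$p_values[["sex_x_ga"]], 0.10)
})

test_that("a null candidate is retained at roughly the screening level", {
  # constant-hazard truth: the sex effect is exactly zero, so the forward
  # rule should keep it with probability near alpha = 0.10
  m0 <- digirop_model()
  m0$estimates[] <- 0
  m0$estimates["intercept"] <- log(0.012)
  kept <- vapply(1:100, function(r) {
    co <- simulate_cohort(n = 400, model = m0, seed = 100 + r)
    rows <- expand_person_time(co, interval_width = 4)
    out <- interaction_screen(rows, base_terms = "intercept",
                              candidates = list(sex = "sex"))
    "sex" %in% out$retained
  }, logical(1))
  rate <- mean(kept)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.22)
})
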