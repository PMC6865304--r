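test_that("simulated cohorts are reproducible and schema-valid", {
  c1 <- simulate_cohort(n = 300, seed = 5)
  c2 <- simulate_cohort(n = 300, seed = 5)
  expect_identical(c1, c2)
  expect_true(all(c1$sex %in% 1:2))
  expect_true(all(c1$ga_weeks >= 24 & c1$ga_weeks < 31))
  expect_true(all(c1$bwsds >= -5 & c1$bwsds <= 3))
  expect_true(all(c1$time_weeks > 0 & c1$time_weeks <= 20))
  expect_error(simulate_cohort(n = 10), "seed")
})

test_that("a vanishing hazard censors everyone", {
  m0 <- digirop_model()
  m0$estimates[] <- 0
  m0$estimates["intercept"] <- -50
  co <- simulate_cohort(n = 200, model = m0, seed = 6)
  expect_true(all(co$event == 0L))
  expect_true(all(co$time_weeks == 20))
  expect_equal(treated_fraction(co), 0)
})

test_that("constant hazard reproduces the exponential distribution", {
  lambda <- 0.25
  m0 <- digirop_model()
  m0$estimates[] <- 0
  m0$estimates["intercept"] <- log(lambda)
  co <- simulate_cohort(n = 50000, model = m0, seed = 7, censor_time = 1e5)
  expect_true(all(co$event == 1L))
  expect_equal(mean(co$time_weeks), 1 / lambda, tolerance = 0.02)
  expect_equal(stats::median(co$time_weeks), log(2) / lambda, tolerance = 0.03)
})

test_that("empirical survival matches analytic S(t) within a 99% DKW band", {
  m <- digirop_model()
  # single covariate pattern so the analytic survival is exact
  ga <- 24 + 3 / 7
  n <- 20000
  co <- simulate_cohort(n = n, model = m, seed = 8,
                        ga_weights = c("24" = 1), p_boy = 1,
                        bwsds_mean = -3, bwsds_sd = 1e-9,
                        censor_time = 1e5)
  co <- co[abs(co$ga_weeks - ga) < 1e-9, ]   # one GA+days cell
  inf <- data.frame(ga_weeks = ga, sex = 1L, bwsds = co$bwsds[1])
  eps <- sqrt(log(2 / 0.01) / (2 * nrow(co)))   # DKW at alpha = 0.01
  for (tt in c(4, 8, 10, 12, 14, 18)) {
    S_emp <- mean(co$time_weeks > tt)
    S_true <- exp(-cumulative_hazard(inf, tt, m, allow_extrapolation = TRUE))
    expect_lt(abs(S_emp - S_true), eps)
  }
})

test_that("inverse-CDF event times agree with rejection sampling", {
  m <- digirop_model()
  inf <- data.frame(ga_weeks = 25, sex = 1L, bwsds = -2)
  n <- 10000
  # rejection sampler from the event-time density f(t) = h(t) S(t) on
  # [0, 20]; simulated event times censored at 20 have the same shape
  dens <- function(tt) {
    reps <- inf[rep(1, length(tt)), , drop = FALSE]
    exp(log_hazard(reps, tt, m)) * exp(-cumulative_hazard(reps, tt, m))
  }
  fmax <- max(dens(seq(0, 20, length.out = 800))) * 1.05
  set.seed(99)
  rej <- numeric(0)
  while (length(rej) < n) {
    cand <- runif(4 * n, 0, 20)
    keep <- runif(4 * n) < dens(cand) / fmax
    rej <- c(rej, cand[keep])
  }
  rej <- rej[seq_len(n)]
  co <- simulate_cohort(n = 60000, model = m, seed = 100,
                        ga_weights = c("25" = 1), p_boy = 1,
                        bwsds_mean = -2, bwsds_sd = 1e-12)
  co <- co[co$event == 1L & abs(co$ga_weeks - 25) < 1e-9, ]
  ks <- suppressWarnings(stats::ks.test(rej, co$time_weeks))
  expect_gt(ks$p.value, 0.01)
})

test_that("treated fraction sits in the realistic envelope and responds to the hazard", {
  m <- digirop_model()
  co <- simulate_cohort(n = 50000, model = m, seed = 12)
  fr <- treated_fraction(co)
  expect_gte(fr, 0.03)
  expect_lte(fr, 0.12)
  m2 <- m
  m2$estimates["intercept"] <- m$estimates["intercept"] + log(2)
  co2 <- simulate_cohort(n = 50000, model = m2, seed = 12)
  expect_gt(treated_fraction(co2), fr)
  expect_error(treated_fraction(co[0, ]), "empty")
})

test_that("the simulate method wraps the cohort generator", {
  m <- digirop_model()
  cs <- simulate(m, nsim = 2, seed = 40, n = 50)
  expect_length(cs, 2)
  expect_identical(cs[[1]], simulate_cohort(n = 50, model = m, seed = 40))
  expect_false(identical(cs[[1]], cs[[2]]))
})
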