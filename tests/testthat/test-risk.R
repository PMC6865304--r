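m <- digirop_model()

test_that("log hazard is continuous at the knots", {
  inf <- random_infants(1000, seed = 11)
  for (k in c(8, 12)) {
    lo <- log_hazard(inf, k - 1e-9, m)
    hi <- log_hazard(inf, k + 1e-9, m)
    expect_lt(max(abs(hi - lo)), 1e-7)
  }
  # exact equality of the one-sided limits via the segment representation
  seg <- hazard_segments(infant(25, "girl", -1), m)
  jump1 <- (seg$a[1] + seg$b[1] * 8) - (seg$a[2] + seg$b[2] * 8)
  jump2 <- (seg$a[2] + seg$b[2] * 12) - (seg$a[3] + seg$b[3] * 12)
  expect_lt(abs(jump1), 1e-9)
  expect_lt(abs(jump2), 1e-9)
})

test_that("zero coefficients give zero log hazard", {
  m0 <- m
  m0$estimates[] <- 0
  inf <- random_infants(5, seed = 2)
  expect_equal(log_hazard(inf, 7, m0), rep(0, 5))
})

test_that("log-hazard slope between the knots is the printed segment slope plus interactions", {
  inf <- infant(26, "boy", -2)
  slope <- (log_hazard(inf, 11, m) - log_hazard(inf, 9, m)) / 2
  enc <- m$encoding
  b <- coef(m)
  I <- b[["t_x_ga_24_27"]] * (min(26, 27) - enc$c_ga_main) +
    b[["t_x_bwsds_le_m1"]] * (min(-2, -1) - enc$c_bwsds) +
    b[["t_x_bwsds_gt_m1"]] * max(-2 + 1, 0)
  expect_equal(unname(slope), 0.3618 + unname(I), tolerance = 1e-10)
})

test_that("closed-form cumulative hazard matches numerical quadrature", {
  # random covariates and ages against adaptive quadrature of exp(log h)
  inf <- random_infants(25, seed = 33)
  set.seed(34)
  ts <- runif(25, 0.5, 20)
  H <- cumulative_hazard(inf, ts, m)
  Hq <- vapply(seq_len(25), function(i) {
    stats::integrate(function(u) exp(log_hazard(inf[i, , drop = FALSE], u, m)),
                     0, ts[i], rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
  expect_lt(max(abs(H - Hq) / pmax(Hq, 1e-300)), 1e-8)
})

test_that("constant-hazard limit of the segment integral is exact", {
  # b = 0, a = log(0.1), length 5 -> H = 0.5 via an intercept-only model
  m0 <- m
  m0$estimates[] <- 0
  m0$estimates["intercept"] <- log(0.1)
  inf <- infant(25, "boy", 0)
  expect_equal(cumulative_hazard(inf, 5, m0), 0.5)
  # and F(t) = 1 - exp(-e^a t) closed form at several ages
  for (tt in c(1, 8.5, 20))
    expect_equal(cumulative_risk(inf, tt, m0), 1 - exp(-0.1 * tt))
})

test_that("cumulative risk is a probability, monotone, zero at birth", {
  inf <- random_infants(50, seed = 44)
  grid <- seq(0, 20, by = 0.5)
  for (i in c(1, 17, 50)) {
    F <- vapply(grid, function(tt)
      cumulative_risk(inf[i, , drop = FALSE], tt, m), numeric(1))
    expect_equal(F[1], 0)
    expect_true(all(diff(F) >= -1e-12))
    expect_true(all(F >= 0 & F <= 1))
  }
})

test_that("extrapolation past the horizon is refused unless overridden", {
  inf <- infant(25, "boy", 0)
  expect_error(cumulative_risk(inf, 25, m), "horizon")
  expect_silent(cumulative_risk(inf, 25, m, allow_extrapolation = TRUE))
})

test_that("sex hazard ratio is time-invariant and matches the hazard ratio of the curves", {
  for (ga in c(24.5, 26, 28, 30)) {
    hr <- girl_vs_boy_hr(ga, m)
    girl <- data.frame(ga_weeks = ga, sex = 2L, bwsds = -0.5)
    boy <- data.frame(ga_weeks = ga, sex = 1L, bwsds = -0.5)
    for (tt in c(2, 9, 15))
      expect_equal(unname(exp(log_hazard(girl, tt, m) - log_hazard(boy, tt, m))),
                   unname(hr), tolerance = 1e-12)
  }
  # at the centering GA the interaction vanishes: HR = exp(beta_sex)
  expect_equal(unname(girl_vs_boy_hr(28, m)), exp(-0.9385))
})

test_that("risk curve is consistent with pointwise risk and ordered in GA", {
  inf <- infant(24, "girl", 0)
  rc <- risk_curve(inf, m, grid = c(0, 5, 10, 20))
  expect_equal(rc$cum_risk[1], 0)
  expect_equal(rc$cum_risk[3], cumulative_risk(inf, 10, m))
  expect_error(risk_curve(inf, m, grid = numeric(0)), "non-empty")
  # lower GA dominates pointwise for the same sex/BWSDS
  grid <- seq(0.5, 20, by = 0.5)
  r24 <- risk_curve(infant(24, "boy", 0), m, grid)$cum_risk
  r25 <- risk_curve(infant(25, "boy", 0), m, grid)$cum_risk
  expect_true(all(r24 >= r25))
})
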