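test_that("suggested first-exam ages follow the floor-minus-one rule", {
  expect_equal(suggested_first_exam(7.9), 6L)
  expect_equal(suggested_first_exam(8.3), 7L)
  expect_equal(suggested_first_exam(8.0), 7L)
  expect_equal(suggested_first_exam(c(8.3, 7.4, 7.0, 7.9, 7.6, 8.0)),
               c(7L, 6L, 6L, 6L, 6L, 7L))
  expect_error(suggested_first_exam(0.9), "> 1")
  # idempotent within a unit interval of the input
  expect_equal(suggested_first_exam(7.0 + c(0, 0.37, 0.99)), rep(6L, 3))
})

test_that("risk-threshold age matches a single-infant bisection oracle", {
  m <- digirop_model()
  inf <- data.frame(ga_weeks = 25, sex = 1L, bwsds = -1)
  age <- risk_threshold_age(inf, m, threshold = 0.001)
  # bisection on F(t) = threshold, independent of the grid search
  f <- function(tt) cumulative_risk(inf, tt, m) - 0.001
  lo <- 0; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lte(as.numeric(age), lo)
  expect_lt(lo - as.numeric(age), 0.1 + 1e-9)   # within one grid step
  expect_true(attr(age, "reached"))
})

test_that("risk-threshold age is monotone in threshold and GA, and flags non-crossing", {
  m <- digirop_model()
  inf <- data.frame(ga_weeks = 25, sex = 1L, bwsds = -1)
  a1 <- risk_threshold_age(inf, m, threshold = 0.001)
  a2 <- risk_threshold_age(inf, m, threshold = 0.01)
  expect_lte(as.numeric(a1), as.numeric(a2))
  never <- risk_threshold_age(inf, m, threshold = 1.0)
  expect_equal(as.numeric(never), 20)
  expect_false(attr(never, "reached"))
  # population average of one infant equals that infant
  pop1 <- risk_threshold_age(inf[c(1, 1, 1), ], m, threshold = 0.001)
  expect_equal(as.numeric(pop1), as.numeric(a1))
  # threshold ages increase across GA strata on a synthetic population
  co <- simulate_cohort(n = 4000, seed = 17)
  ages <- vapply(c(24, 26, 28, 30), function(g) {
    strat <- co[floor(co$ga_weeks) == g, c("ga_weeks", "sex", "bwsds")]
    as.numeric(risk_threshold_age(strat, m, threshold = 0.001))
  }, numeric(1))
  expect_true(all(diff(ages) >= 0))
})

test_that("avoided-visit accounting matches hand counts and stays in [0, 1]", {
  co <- data.frame(id = 1, ga_weeks = 27.2, sex = 1L, bwsds = 0,
                   event = 0L, time_weeks = 14)
  out <- avoided_visits(co, old_start = c("27" = 4), new_start = c("27" = 6))
  expect_equal(out$avoided, 2)
  expect_equal(out$total, 10)
  expect_equal(out$fraction, 0.2)
  # identical schedules avoid nothing
  same <- avoided_visits(co, c("27" = 4), c("27" = 4))
  expect_equal(same$avoided, 0)
  expect_equal(same$fraction, 0)
  # an earlier new start never counts negatively
  earlier <- avoided_visits(co, c("27" = 6), c("27" = 4))
  expect_equal(earlier$avoided, 0)
  # random schedules keep the fraction in [0, 1]
  co2 <- simulate_cohort(n = 300, seed = 23)
  wk <- as.character(24:30)
  set.seed(24)
  for (r in 1:5) {
    old <- stats::setNames(runif(7, 2, 8), wk)
    new <- stats::setNames(runif(7, 2, 10), wk)
    fr <- avoided_visits(co2, old, new)$fraction
    expect_gte(fr, 0)
    expect_lte(fr, 1)
  }
  expect_error(avoided_visits(co, c("26" = 4), c("26" = 5)), "27")
})

test_that("the schedule table assembles per-GA rules", {
  co <- simulate_cohort(n = 3000, seed = 29)
  tab <- schedule_table(co, digirop_model())
  expect_true(all(tab$ga_week %in% 24:30))
  i <- !is.na(tab$min_treatment_age)
  expect_equal(tab$suggested_first_exam_postnatal[i],
               as.integer(floor(tab$min_treatment_age[i]) - 1))
  expect_equal(tab$suggested_first_exam_postmenstrual[i],
               tab$suggested_first_exam_postnatal[i] + tab$ga_week[i])
  expect_true(all(diff(tab$risk_threshold_age) >= 0))
})
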