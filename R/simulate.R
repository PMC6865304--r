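#' Simulate a preterm screening cohort from the hazard model
#'
#' Generates a cohort shaped like a national very-preterm screening
#' population: gestational age drawn from per-week weights (default: the
#' per-GA totals of a Swedish national register cohort, GA 24-30 weeks,
#' with days uniform within the week), about 55% boys, and a BWSDS mix that
#' is roughly standard normal with a left-shifted tail (normal with mean
#' -0.5, SD 1.3, truncated to [-5, 3]) reflecting the growth restriction
#' common in this population.  Event times are drawn exactly from the
#' model's piecewise log-linear hazard by inverse-CDF sampling (the
#' cumulative hazard is inverted segment by segment in closed form), then
#' administratively censored.
#'
#' @param n cohort size.
#' @param model `digirop` model supplying the true hazard (default the
#'   published coefficient set).
#' @param ga_weights named numeric: sampling weights for completed GA weeks
#'   24-30.
#' @param p_boy probability of a boy, default 0.546.
#' @param bwsds_mean,bwsds_sd,bwsds_range truncated-normal BWSDS parameters.
#' @param censor_time administrative censoring age in weeks (default 20), a
#'   scalar or a function of the GA vector (GA-dependent screening end).
#' @param seed integer seed; required.
#' @return cohort data frame: `id`, `ga_weeks`, `sex`, `bwsds`, `event`,
#'   `time_weeks`.
#' @examples
#' co <- simulate_cohort(n = 500, seed = 42)
#' treated_fraction(co)
#' @export
simulate_cohort <- function(n, model = digirop_model(),
                            ga_weights = c("24" = 436, "25" = 620,
                                           "26" = 801, "27" = 949,
                                           "28" = 1179, "29" = 1479,
                                           "30" = 1791),
                            p_boy = 0.546, bwsds_mean = -0.5, bwsds_sd = 1.3,
                            bwsds_range = c(-5, 3), censor_time = 20, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n >= 1, p_boy >= 0, p_boy <= 1, all(ga_weights >= 0))
  set.seed(seed)
  ga_wk <- as.numeric(sample(names(ga_weights), n, replace = TRUE,
                             prob = ga_weights / sum(ga_weights)))
  ga <- ga_wk + sample(0:6, n, replace = TRUE) / 7
  sex <- ifelse(stats::runif(n) < p_boy, 1L, 2L)
  # truncated normal by inverse CDF
  plo <- stats::pnorm(bwsds_range[1], bwsds_mean, bwsds_sd)
  phi <- stats::pnorm(bwsds_range[2], bwsds_mean, bwsds_sd)
  bwsds <- stats::qnorm(stats::runif(n, plo, phi), bwsds_mean, bwsds_sd)
  infants <- data.frame(ga_weeks = ga, sex = sex, bwsds = bwsds)

  cens <- if (is.function(censor_time)) censor_time(ga) else
    rep_len(censor_time, n)
  if (any(cens <= 0)) stop("censor_time must be positive", call. = FALSE)

  u <- stats::runif(n)
  ev_time <- .sample_event_times(infants, model, -log1p(-u))
  event <- as.integer(is.finite(ev_time) & ev_time <= cens)
  data.frame(id = seq_len(n), ga_weeks = ga, sex = sex, bwsds = bwsds,
             event = event,
             time_weeks = ifelse(event == 1L, ev_time, cens))
}

# invert H(t) = target segment by segment, in closed form; Inf when the
# total cumulative hazard never reaches the target
.sample_event_times <- function(infants, model, target) {
  sm <- .hazard_seg_mat(infants, model)
  n <- nrow(infants)
  starts <- c(0, sm$k1, sm$k2)
  ends <- c(sm$k1, sm$k2, Inf)
  t_out <- rep(Inf, n)
  rem <- target
  done <- rep(FALSE, n)
  for (s in 1:3) {
    a <- sm$a[, s]; b <- sm$b[, s]
    t1 <- starts[s]; t2 <- ends[s]
    Hseg <- .segment_integral(a, b, t1, pmin(t2, 1e6))
    hit <- !done & rem <= Hseg
    if (any(hit)) {
      ah <- a[hit]; bh <- b[hit]; rh <- rem[hit]
      const <- abs(bh) < 1e-10
      tt <- numeric(sum(hit))
      # constant hazard: t = t1 + rem / exp(a)
      tt[const] <- t1 + rh[const] / exp(ah[const])
      # else solve (exp(a+bt) - exp(a+b t1))/b = rem
      if (any(!const)) {
        aa <- ah[!const]; bb <- bh[!const]
        tt[!const] <- (log(bb * rh[!const] + exp(aa + bb * t1)) - aa) / bb
      }
      t_out[hit] <- tt
      done[hit] <- TRUE
    }
    rem <- rem - Hseg
  }
  t_out
}

#' Fraction of a cohort treated for ROP
#' @param cohort cohort data frame with an `event` column.
#' @return proportion of records with `event == 1`.
#' @export
treated_fraction <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  mean(cohort$event == 1L)
}

#' Simulate cohorts from a digirop model
#'
#' @param object a `digirop` model.
#' @param nsim number of cohorts.
#' @param seed integer seed (cohort `i` uses `seed + i - 1`).
#' @param n cohort size per replicate.
#' @param ... passed to [simulate_cohort()].
#' @return a list of cohort data frames (a single data frame when
#'   `nsim = 1`).
#' @export
simulate.digirop <- function(object, nsim = 1, seed, n = 1000, ...) {
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(n = n, model = object, seed = seed + i - 1, ...))
  if (nsim == 1L) out[[1]] else out
}
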