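#' Hazard segments for one infant
#'
#' Under the model the log hazard is piecewise linear in postnatal age:
#' `log h(t) = a + b * t` on each of the three segments delimited by the
#' postnatal-age knots.  This returns the per-segment intercepts and slopes,
#' the quantity the closed-form cumulative hazard integrates.
#'
#' @param infants one-row data frame of infant covariates.
#' @param model a `digirop` model.
#' @param horizon end of the last segment in weeks (default 20).
#' @return data frame with columns `t_start`, `t_end`, `a`, `b`.
#' @export
hazard_segments <- function(infants, model = digirop_model(), horizon = 20) {
  infants <- validate_infants(infants)
  if (nrow(infants) != 1L)
    stop("hazard_segments() takes a single infant", call. = FALSE)
  sm <- .hazard_seg_mat(infants, model)
  seg <- data.frame(t_start = c(0, sm$k1, sm$k2),
                    t_end = c(sm$k1, sm$k2, horizon),
                    a = drop(sm$a), b = drop(sm$b))
  seg[seg$t_start < horizon, , drop = FALSE]
}

# vectorized per-infant segment parameters: a, b are n x 3 matrices for the
# three postnatal-age segments [0,k1), [k1,k2), [k2, Inf)
.hazard_seg_mat <- function(infants, model) {
  enc <- model$encoding
  k1 <- enc$t_knots[1]; k2 <- enc$t_knots[2]
  b <- unname(model$estimates)
  ga <- .ga_basis(infants$ga_weeks, enc)
  bw <- .bwsds_basis(infants$bwsds, enc)
  # time-free part of the linear predictor
  C <- b[1] + b[5] * ga$lo + b[6] * ga$hi + b[7] * infants$sex +
    b[8] * bw$lo + b[9] * bw$hi +
    b[12] * infants$sex * (infants$ga_weeks - enc$c_ga_sex)
  # summed interaction slope multiplying the interaction time quantity
  I <- b[10] * ga$lo + b[11] * ga$hi + b[13] * bw$lo + b[14] * bw$hi
  # interaction time TT(t) = alpha_s + gamma_s * t per segment
  if (enc$t_interaction_form == "raw") {
    alpha <- c(0, 0, 0); gamma <- c(1, 1, 1)
  } else {
    alpha <- c(0, k1, k1); gamma <- c(1, 0, 0)
  }
  bt <- b[2:4]
  a0 <- cbind(C, C + bt[1] * k1 - bt[2] * k1,
              C + bt[1] * k1 + bt[2] * (k2 - k1) - bt[3] * k2)
  amat <- a0 + outer(I, alpha)
  bmat <- matrix(bt, nrow(infants), 3, byrow = TRUE) + outer(I, gamma)
  list(a = amat, b = bmat, k1 = k1, k2 = k2)
}

#' Log hazard of ROP treatment
#'
#' @param infants data frame of infant covariates.
#' @param t postnatal age(s), weeks; scalar or one per infant.
#' @param model a `digirop` model.
#' @return log rate (events per week, natural log).
#' @export
log_hazard <- function(infants, t, model = digirop_model()) {
  X <- design_row(infants, t, model$encoding)
  drop(X %*% model$estimates)
}

# integral of exp(a + b u) over [t1, t2]; constant-hazard limit guards
# catastrophic cancellation at tiny |b|
.segment_integral <- function(a, b, t1, t2) {
  ifelse(abs(b) < 1e-10,
         exp(a) * (t2 - t1),
         (exp(a + b * t2) - exp(a + b * t1)) / b)
}

#' Cumulative hazard H(t)
#'
#' Closed-form integral of the piecewise log-linear hazard from birth to
#' postnatal age `t`.  Ages beyond the model horizon are refused by default
#' because the last hazard segment is an extrapolation there.
#'
#' @inheritParams log_hazard
#' @param horizon maximum supported age (weeks), default 20.
#' @param allow_extrapolation set `TRUE` to evaluate past the horizon.
#' @return dimensionless cumulative hazard, vectorized over infants.
#' @export
cumulative_hazard <- function(infants, t, model = digirop_model(),
                              horizon = 20, allow_extrapolation = FALSE) {
  infants <- validate_infants(infants)
  n <- nrow(infants)
  if (length(t) == 1L) t <- rep(t, n)
  if (length(t) != n)
    stop("'t' must be a scalar or one age per infant", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (!allow_extrapolation && any(t > horizon + 1e-12))
    stop(sprintf("t exceeds the %g-week model horizon; set allow_extrapolation = TRUE to override", horizon),
         call. = FALSE)
  sm <- .hazard_seg_mat(infants, model)
  starts <- c(0, sm$k1, sm$k2)
  H <- numeric(n)
  for (s in 1:3) {
    hi <- pmin(t, c(sm$k1, sm$k2, Inf)[s])
    use <- t > starts[s]
    if (any(use))
      H[use] <- H[use] + .segment_integral(sm$a[use, s], sm$b[use, s],
                                           starts[s], hi[use])
  }
  H
}

#' Cumulative risk F(t) = 1 - exp(-H(t))
#'
#' The probability of needing ROP treatment by postnatal age `t`.
#'
#' @inheritParams cumulative_hazard
#' @return probability in `[0, 1]`, vectorized over infants.
#' @examples
#' m <- digirop_model()
#' cumulative_risk(infant(24, "girl", -3), 20, m)   # ~0.60
#' cumulative_risk(infant(25, "boy", 0), 20, m)     # ~0.17
#' @export
cumulative_risk <- function(infants, t, model = digirop_model(),
                            horizon = 20, allow_extrapolation = FALSE) {
  1 - exp(-cumulative_hazard(infants, t, model, horizon, allow_extrapolation))
}

#' Girl-versus-boy hazard ratio at a given gestational age
#'
#' The sex contrast is `(2 - 1) * (beta_sex + beta_sexGA * (ga - c))`, where
#' `c` is the GA centering of the sex-by-GA product; it does not involve
#' postnatal age, so the ratio is constant over follow-up.
#'
#' @param ga_weeks gestational age(s) in decimal weeks.
#' @param model a `digirop` model.
#' @return hazard ratio(s), girls relative to boys.
#' @examples
#' girl_vs_boy_hr(25)  # ~0.83
#' girl_vs_boy_hr(27)  # ~0.50
#' @export
girl_vs_boy_hr <- function(ga_weeks, model = digirop_model()) {
  if (any(!is.finite(ga_weeks)))
    stop("ga_weeks must be finite", call. = FALSE)
  b <- model$estimates
  exp(b[["sex"]] + b[["sex_x_ga"]] * (ga_weeks - model$encoding$c_ga_sex))
}

#' Cumulative risk curve over a grid of postnatal ages
#'
#' @param infants one-row data frame of infant covariates.
#' @param model a `digirop` model.
#' @param grid postnatal ages in weeks, within `[0, horizon]`.
#' @param horizon model horizon, default 20 weeks.
#' @return data frame of class `digirop_risk` with columns `t_weeks` and
#'   `cum_risk` (plus `lower`/`upper` once [risk_band()] adds them).
#' @export
risk_curve <- function(infants, model = digirop_model(),
                       grid = seq(0, 20, by = 0.1), horizon = 20) {
  infants <- validate_infants(infants)
  if (nrow(infants) != 1L)
    stop("risk_curve() takes a single infant", call. = FALSE)
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0 | grid > horizon))
    stop(sprintf("grid must lie in [0, %g]", horizon), call. = FALSE)
  F <- vapply(grid, function(tt) cumulative_risk(infants, tt, model, horizon),
              numeric(1))
  out <- data.frame(t_weeks = grid, cum_risk = F)
  attr(out, "infant") <- infants
  class(out) <- c("digirop_risk", "data.frame")
  out
}

#' @export
print.digirop_risk <- function(x, ...) {
  inf <- attr(x, "infant")
  cat(sprintf("Cumulative ROP-treatment risk curve: GA %s, %s, BWSDS %g\n",
              format_ga(inf$ga_weeks), c("boy", "girl")[inf$sex], inf$bwsds))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x), "grid points; F(",
                       max(x$t_weeks), ") = ",
                       sprintf("%.3f", x$cum_risk[nrow(x)]), "\n", sep = "")
  invisible(x)
}

#' Plot a cumulative risk curve
#' @param x a `digirop_risk` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.digirop_risk <- function(x, ...) {
  inf <- attr(x, "infant")
  graphics::plot(x$t_weeks, x$cum_risk, type = "l", lwd = 2,
                 xlab = "Postnatal age (weeks)",
                 ylab = "Cumulative risk of ROP treatment",
                 ylim = c(0, max(x$upper %||% x$cum_risk, x$cum_risk) * 1.05),
                 main = sprintf("GA %s, %s, BWSDS %g", format_ga(inf$ga_weeks),
                                c("boy", "girl")[inf$sex], inf$bwsds), ...)
  if (!is.null(x$lower)) {
    graphics::lines(x$t_weeks, x$lower, lty = 2)
    graphics::lines(x$t_weeks, x$upper, lty = 2)
  }
  invisible(x)
}

#' Plot method for digirop models: risk curves for reference infants
#' @param x a `digirop` model.
#' @param infants data frame of infants to draw (default: boys and girls at
#'   GA 24 and 27 weeks with BWSDS 0).
#' @param ... passed to plot.
#' @export
plot.digirop <- function(x, infants = NULL, ...) {
  if (is.null(infants))
    infants <- data.frame(ga_weeks = c(24, 24, 27, 27), sex = c(1, 2, 1, 2),
                          bwsds = 0)
  infants <- validate_infants(infants)
  grid <- seq(0, 20, by = 0.25)
  curves <- lapply(seq_len(nrow(infants)), function(i)
    risk_curve(infants[i, , drop = FALSE], x, grid))
  ylim <- c(0, max(vapply(curves, function(cc) max(cc$cum_risk), 1)) * 1.05)
  graphics::plot(NULL, xlim = range(grid), ylim = ylim,
                 xlab = "Postnatal age (weeks)",
                 ylab = "Cumulative risk of ROP treatment", ...)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$t_weeks, curves[[i]]$cum_risk, col = i, lwd = 2)
  graphics::legend("topleft", bty = "n", col = seq_along(curves), lwd = 2,
                   legend = sprintf("GA %s %s BWSDS %g",
                                    format_ga(infants$ga_weeks),
                                    c("boy", "girl")[infants$sex],
                                    infants$bwsds))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
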