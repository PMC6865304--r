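#' The published DIGIROP-Birth model object
#'
#' Returns the fitted risk model for infants born at GA 24 to 30 weeks as a
#' `digirop` object: the 14 published log-hazard coefficients with their
#' standard errors, a coefficient covariance matrix, and the calibrated
#' basis encoding.  The hazard is piecewise log-linear in postnatal age
#' (knots at 8 and 12 weeks), with piecewise-linear GA (knot 27 weeks) and
#' BWSDS (knot -1 SDS) effects, a sex effect, and postnatal-age and
#' sex-by-GA interactions.
#'
#' The published report gives standard errors but not the full coefficient
#' covariance, so the default covariance here is the synthetic diagonal
#' `diag(se^2)`.  That is sufficient for single-coefficient inference and
#' for exercising the bootstrap machinery, but understates the correlation
#' structure a full fit would carry; refit on cohort data with
#' [digirop_fit()] to obtain a complete covariance.
#'
#' @param covariance optional 14x14 covariance matrix overriding the
#'   synthetic diagonal default.
#' @param encoding a [digirop_encoding()]; default is the calibrated one.
#' @return An object of class `digirop`.
#' @examples
#' m <- digirop_model()
#' coef(m)[1:4]
#' cumulative_risk(infant(24, "girl", -3), t = 20, model = m)
#' @export
digirop_model <- function(covariance = NULL, encoding = digirop_encoding()) {
  est <- c(-20.1666, 1.7331, 0.3618, -0.3788, -0.8210, 0.7266, -0.9385,
           0.1521, -1.0401, 0.0227, -0.1360, -0.2505, -0.0371, 0.0728)
  se <- c(4.9219, 0.6129, 0.0992, 0.0857, 0.3353, 0.7302, 0.3054,
          0.2656, 0.4710, 0.0230, 0.0627, 0.1066, 0.0199, 0.0349)
  names(est) <- names(se) <- digirop_term_names()
  if (is.null(covariance)) {
    covariance <- diag(se^2)
    dimnames(covariance) <- list(names(est), names(est))
    attr(covariance, "synthetic") <- TRUE
  }
  new_digirop(est, se, covariance, encoding)
}

# low-level constructor + invariant checks shared by the fixture and the fit
new_digirop <- function(estimates, ses, covariance = NULL,
                        encoding = digirop_encoding(), fit = NULL) {
  nm <- digirop_term_names()
  if (length(estimates) != 14L || length(ses) != 14L)
    stop("a digirop model has exactly 14 coefficients", call. = FALSE)
  if (any(!is.finite(estimates)))
    stop("estimates must be finite", call. = FALSE)
  if (any(!is.na(ses) & (!is.finite(ses) | ses < 0)))
    stop("SEs must be non-negative (or NA when no covariance is available)",
         call. = FALSE)
  names(estimates) <- names(ses) <- nm
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == c(14L, 14L)))
      stop("covariance must be 14x14", call. = FALSE)
    if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
      stop("covariance must be symmetric", call. = FALSE)
    ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1))
      stop("covariance must be positive semi-definite", call. = FALSE)
    dse <- sqrt(pmax(diag(covariance), 0))
    rel <- abs(dse - ses) / pmax(ses, .Machine$double.eps)
    chk <- !is.na(ses) & ses > 0
    if (any(chk) && max(rel[chk]) > 1e-6)
      warning("diag(covariance) inconsistent with ses^2 (max rel. err ",
              signif(max(rel[chk]), 3), ")")
    dimnames(covariance) <- list(nm, nm)
  }
  structure(list(estimates = estimates, ses = ses, covariance = covariance,
                 encoding = encoding, fit = fit),
            class = "digirop")
}

#' @export
coef.digirop <- function(object, ...) object$estimates

#' @export
vcov.digirop <- function(object, ...) {
  if (is.null(object$covariance))
    stop("model carries no covariance matrix", call. = FALSE)
  object$covariance
}

#' @export
print.digirop <- function(x, ...) {
  cat("DIGIROP piecewise log-linear hazard model (ROP treatment)\n")
  src <- if (is.null(x$fit)) "published coefficient set" else
    sprintf("fitted: %d person-time rows, %d events, loglik %.2f",
            x$fit$n_rows, x$fit$n_events, x$fit$loglik)
  cat("  ", src, "\n", sep = "")
  if (isTRUE(attr(x$covariance, "synthetic")))
    cat("  covariance: synthetic diagonal from published SEs\n")
  cat("\nCoefficients (log hazard per week):\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
summary.digirop <- function(object, ...) {
  z <- object$estimates / object$ses
  tab <- cbind(Estimate = object$estimates, `Std. Error` = object$ses,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               HR = exp(object$estimates))
  out <- list(coefficients = tab, encoding = object$encoding, fit = object$fit)
  class(out) <- "summary.digirop"
  out
}

#' @export
print.summary.digirop <- function(x, ...) {
  cat("DIGIROP model summary\n\n")
  stats::printCoefmat(x$coefficients[, 1:4], P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$fit))
    cat(sprintf("\n%d person-time rows, %d events, log-likelihood %.3f\n",
                x$fit$n_rows, x$fit$n_events, x$fit$loglik))
  invisible(x)
}

#' Predict cumulative ROP-treatment risk for infants
#'
#' @param object a `digirop` model.
#' @param newdata data frame of infant covariates (`ga_weeks`, `sex`,
#'   `bwsds`); default is a reference infant grid of one row per printed
#'   worked example.
#' @param times postnatal ages (weeks) at which to evaluate, default 20.
#' @param type `"risk"` (cumulative risk F(t)), `"cumhaz"` (H(t)) or
#'   `"hazard"` (h(t)).
#' @param ... unused.
#' @return numeric matrix, infants x times (dropped to a vector when one
#'   dimension is 1).
#' @export
predict.digirop <- function(object, newdata, times = 20,
                            type = c("risk", "cumhaz", "hazard"), ...) {
  type <- match.arg(type)
  newdata <- validate_infants(newdata)
  fun <- switch(type, risk = cumulative_risk, cumhaz = cumulative_hazard,
                hazard = function(inf, t, model) exp(log_hazard(inf, t, model)))
  out <- vapply(times, function(tt) fun(newdata, tt, object),
                numeric(nrow(newdata)))
  out <- matrix(out, nrow = nrow(newdata),
                dimnames = list(NULL, paste0("t", times)))
  drop(out)
}
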