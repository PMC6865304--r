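#' Draw coefficient vectors from the model's sampling distribution
#'
#' Parametric-bootstrap uncertainty: coefficient vectors are drawn from a
#' multivariate normal centered at the estimates with the model's
#' covariance matrix (Cholesky factorization, with a symmetric-eigen
#' fallback when the covariance is only semi-definite).
#'
#' @param model a `digirop` model with covariance.
#' @param n_draws number of draws, default 1000.
#' @param seed integer seed; required for reproducibility.
#' @return `n_draws` x 14 matrix of coefficient vectors.
#' @export
sample_parameters <- function(model, n_draws = 1000, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  V <- vcov(model)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
    stop("covariance is not positive semi-definite", call. = FALSE)
  R <- tryCatch(chol(V), error = function(e)
    t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(V))))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * 14L), nrow = n_draws)
  draws <- Z %*% R + matrix(model$estimates, n_draws, 14L, byrow = TRUE)
  colnames(draws) <- digirop_term_names()
  draws
}

#' Cumulative-risk curve with a parametric-bootstrap confidence band
#'
#' At every grid point the cumulative risk is recomputed under each drawn
#' coefficient vector; the band is the 2.5/97.5 percentile of those draws
#' (or a normal approximation on request).  The point estimate always
#' comes from the original coefficients, never the draw mean.
#'
#' @param infants one-row data frame of infant covariates.
#' @param model a `digirop` model with covariance.
#' @param grid postnatal ages in weeks.
#' @param n_draws number of coefficient draws, default 1000.
#' @param seed integer seed.
#' @param level confidence level, default 0.95.
#' @param method `"percentile"` (default) or `"normal"` (mean +/- z*sd of
#'   the draws).
#' @param draws optional precomputed matrix from [sample_parameters()]
#'   (then `n_draws`/`seed` are ignored).
#' @return `digirop_risk` data frame with `lower` and `upper` columns.
#' @export
risk_band <- function(infants, model = digirop_model(),
                      grid = seq(0, 20, by = 0.5), n_draws = 1000, seed,
                      level = 0.95, method = c("percentile", "normal"),
                      draws = NULL) {
  method <- match.arg(method)
  infants <- validate_infants(infants)
  if (nrow(infants) != 1L)
    stop("risk_band() takes a single infant", call. = FALSE)
  if (is.null(draws)) draws <- sample_parameters(model, n_draws, seed)
  if (nrow(draws) < 100) warning("fewer than 100 draws: band will be noisy")

  # F(t) under a coefficient draw is the same closed form; reuse the risk
  # engine by swapping the estimates
  risk_under <- function(beta) {
    m <- model; m$estimates[] <- beta
    vapply(grid, function(tt) cumulative_risk(infants, tt, m), numeric(1))
  }
  Fmat <- apply(draws, 1, risk_under)          # grid x draws
  Fmat <- matrix(Fmat, nrow = length(grid))
  a <- (1 - level) / 2
  point <- vapply(grid, function(tt) cumulative_risk(infants, tt, model),
                  numeric(1))
  if (method == "percentile") {
    lo <- apply(Fmat, 1, stats::quantile, probs = a, names = FALSE)
    hi <- apply(Fmat, 1, stats::quantile, probs = 1 - a, names = FALSE)
  } else {
    z <- stats::qnorm(1 - a)
    mu <- rowMeans(Fmat); sd <- apply(Fmat, 1, stats::sd)
    lo <- pmax(mu - z * sd, 0); hi <- pmin(mu + z * sd, 1)
  }
  out <- data.frame(t_weeks = grid, cum_risk = point, lower = lo, upper = hi)
  attr(out, "infant") <- infants
  attr(out, "n_draws") <- nrow(draws)
  attr(out, "level") <- level
  class(out) <- c("digirop_risk", "data.frame")
  out
}
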