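#' Expand a screening cohort into person-time rows
#'
#' Rate models with time-varying hazards are fitted on person-time data:
#' each infant's follow-up is split into intervals (default 1 week, the
#' screening cadence), each contributing its length as exposure, with the
#' event flag on the final interval of treated infants.  The design row of
#' an interval is evaluated at a representative age `t_eval`.
#'
#' @param cohort data frame with columns `id`, `ga_weeks`, `sex`, `bwsds`,
#'   `event` (0/1, treated or not), `time_weeks` (postnatal age at
#'   treatment or censoring).
#' @param interval_width interval length in weeks, default 1.
#' @param t_eval `"midpoint"` (default; lower discretization bias for
#'   steeply rising hazards) or `"left"`.
#' @return data frame of person-time rows: `id`, `t_start`, `t_end`,
#'   `exposure`, `event`, `t_eval` plus the covariate columns.  Rows with
#'   non-positive follow-up are dropped with a warning naming the ids.
#' @export
expand_person_time <- function(cohort, interval_width = 1,
                               t_eval = c("midpoint", "left")) {
  t_eval <- match.arg(t_eval)
  if (interval_width <= 0) stop("interval_width must be positive", call. = FALSE)
  cohort <- validate_cohort(cohort)
  bad <- !is.finite(cohort$time_weeks) | cohort$time_weeks <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) with non-positive follow-up: id ",
            paste(utils::head(cohort$id[bad], 10), collapse = ", "))
    cohort <- cohort[!bad, , drop = FALSE]
  }
  n_int <- ceiling(cohort$time_weeks / interval_width - 1e-12)
  idx <- rep(seq_len(nrow(cohort)), n_int)
  # interval index within each infant (1-based)
  j <- sequence(n_int)
  t_start <- (j - 1) * interval_width
  t_end <- pmin(j * interval_width, cohort$time_weeks[idx])
  last <- j == n_int[idx]
  out <- data.frame(id = cohort$id[idx], t_start = t_start, t_end = t_end,
                    exposure = t_end - t_start,
                    event = as.integer(last & cohort$event[idx] == 1L),
                    ga_weeks = cohort$ga_weeks[idx], sex = cohort$sex[idx],
                    bwsds = cohort$bwsds[idx])
  out$t_eval <- if (t_eval == "midpoint") (out$t_start + out$t_end) / 2 else out$t_start
  out
}

# cohort schema validation shared by fitting / simulation / schedule code
validate_cohort <- function(cohort) {
  need <- c("id", "ga_weeks", "sex", "bwsds", "event", "time_weeks")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cohort$sex <- normalize_sex(cohort$sex)
  if (!all(cohort$event %in% c(0L, 1L)))
    stop("event must be 0/1", call. = FALSE)
  cohort
}

# Poisson ML on a prepared design matrix with log-exposure offset.
# glm.fit does the IRLS; covariance is the inverse Fisher information
# X' diag(mu) X evaluated at the optimum.
.fit_pt <- function(X, y, exposure, epsilon = 1e-10, maxit = 100) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(),
                   offset = log(exposure),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)))
  mu <- fit$fitted.values
  info <- crossprod(X * sqrt(mu))
  V <- tryCatch(solve(info), error = function(e) NULL)
  list(coef = fit$coefficients,
       vcov = V,
       loglik = sum(stats::dpois(y, mu, log = TRUE)),
       converged = fit$converged,
       n_rows = length(y), n_events = sum(y))
}

#' Fit the hazard model to a cohort by person-time Poisson regression
#'
#' Expands the cohort into person-time rows, builds the 14-component design
#' row at each interval's evaluation age, and maximizes the Poisson
#' likelihood with a log-exposure offset.  The coefficient covariance is
#' the inverse observed information.
#'
#' @inheritParams expand_person_time
#' @param encoding a [digirop_encoding()] defining the design row.
#' @param terms character vector of design columns to include (default all
#'   14; see `digirop_term_names()`); the result is a full `digirop` object
#'   only when all 14 are fitted.
#' @return For the full term set, a `digirop` model whose `$fit` slot
#'   carries the log-likelihood, row/event counts and convergence flag.
#'   For a subset, a bare fit list (`coef`, `vcov`, `loglik`, ...).
#' @examples
#' \dontrun{
#' co <- simulate_cohort(n = 2000, seed = 1)
#' fit <- digirop_fit(co)
#' summary(fit)
#' }
#' @export
digirop_fit <- function(cohort, encoding = digirop_encoding(),
                        interval_width = 1,
                        t_eval = c("midpoint", "left"),
                        terms = digirop_term_names()) {
  rows <- expand_person_time(cohort, interval_width, t_eval)
  fit_person_time(rows, encoding, terms)
}

#' Fit the Poisson rate model on pre-expanded person-time rows
#'
#' @param rows person-time rows from [expand_person_time()].
#' @param encoding a [digirop_encoding()].
#' @param terms design columns to include.
#' @return see [digirop_fit()].
#' @export
fit_person_time <- function(rows, encoding = digirop_encoding(),
                            terms = digirop_term_names()) {
  if (sum(rows$event) < 1L) stop("no events in the data", call. = FALSE)
  bad <- setdiff(terms, digirop_term_names())
  if (length(bad))
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  X <- design_row(rows[, c("ga_weeks", "sex", "bwsds")], rows$t_eval, encoding)
  X <- X[, terms, drop = FALSE]
  f <- .fit_pt(X, rows$event, rows$exposure)
  if (!f$converged)
    warning("Poisson fit did not converge (possible separation)")
  if (length(terms) == 14L && identical(terms, digirop_term_names())) {
    V <- f$vcov
    if (!is.null(V) && (any(!is.finite(V)) || any(diag(V) < 0))) {
      warning("coefficient covariance is ill-conditioned; dropping it")
      V <- NULL
    }
    ses <- if (!is.null(V)) sqrt(diag(V)) else rep(NA_real_, 14)
    new_digirop(f$coef, ses, V, encoding,
                fit = f[c("loglik", "converged", "n_rows", "n_events")])
  } else {
    f
  }
}

#' Hazard ratio with Wald confidence interval for a coefficient contrast
#'
#' @param model a `digirop` model with a covariance matrix.
#' @param contrast numeric 14-vector `c`; the ratio reported is
#'   `exp(c' beta)` with a normal-approximation 95% CI and p-value.
#' @param level confidence level, default 0.95.
#' @return list `hr`, `lower`, `upper`, `p`.
#' @export
wald_hr <- function(model, contrast, level = 0.95) {
  if (length(contrast) != 14L)
    stop("contrast must have length 14", call. = FALSE)
  V <- vcov(model)
  est <- sum(contrast * model$estimates)
  se <- sqrt(drop(t(contrast) %*% V %*% contrast))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) NA_real_ else 2 * stats::pnorm(-abs(est / se))
  list(hr = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
       p = p)
}

#' Forward interaction screening at P < alpha
#'
#' Mirrors the model-building rule used for the published model: starting
#' from the main-effects model, candidate interaction terms are added in a
#' fixed order and kept when their joint Wald test meets `p < alpha`
#' (default 0.10).
#'
#' @param rows person-time rows from [expand_person_time()].
#' @param encoding a [digirop_encoding()].
#' @param base_terms design columns of the base model (default the
#'   intercept, time, GA, sex and BWSDS mains).
#' @param candidates named list of candidate term groups, tested in order.
#' @param alpha retention threshold on the candidate's p-value.
#' @param test `"wald"` (joint chi-square, default) or `"lr"`.
#' @return list with `retained` (names of kept groups), `p_values`, and
#'   `terms` (final design column set).
#' @export
interaction_screen <- function(rows, encoding = digirop_encoding(),
                               base_terms = digirop_term_names()[1:9],
                               candidates = list(
                                 t_x_ga = c("t_x_ga_24_27", "t_x_ga_gt27"),
                                 sex_x_ga = "sex_x_ga",
                                 t_x_bwsds = c("t_x_bwsds_le_m1",
                                               "t_x_bwsds_gt_m1")),
                               alpha = 0.10, test = c("wald", "lr")) {
  test <- match.arg(test)
  current <- base_terms
  retained <- character(0)
  pvals <- stats::setNames(numeric(0), character(0))
  if (!length(candidates))
    return(list(retained = retained, p_values = pvals, terms = current))
  base_fit <- fit_person_time(rows, encoding, current)
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    trial <- c(current, cand)
    f <- tryCatch(fit_person_time(rows, encoding, trial),
                  error = function(e) NULL)
    if (is.null(f) || (is.list(f) && !isTRUE(f$converged) &&
                       !inherits(f, "digirop"))) {
      warning("candidate '", nm, "' skipped (fit failed or did not converge)")
      next
    }
    cf <- if (inherits(f, "digirop"))
      list(coef = f$estimates, vcov = f$covariance, loglik = f$fit$loglik)
    else f
    idx <- match(cand, trial)
    p <- if (test == "wald") {
      b <- cf$coef[idx]
      Vb <- cf$vcov[idx, idx, drop = FALSE]
      stat <- drop(t(b) %*% solve(Vb) %*% b)
      stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
    } else {
      base_now <- fit_person_time(rows, encoding, current)
      ll0 <- if (inherits(base_now, "digirop")) base_now$fit$loglik else base_now$loglik
      stats::pchisq(2 * (cf$loglik - ll0), df = length(idx),
                    lower.tail = FALSE)
    }
    pvals[nm] <- p
    if (is.finite(p) && p < alpha) {
      current <- trial
      retained <- c(retained, nm)
    }
  }
  list(retained = retained, p_values = pvals, terms = current)
}
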