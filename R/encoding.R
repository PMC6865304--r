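#' Basis encoding for the DIGIROP-Birth design row
#'
#' The hazard model is log-linear in a 14-component design row built from
#' postnatal age and the birth covariates.  Postnatal age, gestational age
#' (GA) and the birth-weight SD score (BWSDS) each enter as piecewise-linear
#' splines in segment-slope form, so every printed coefficient is the
#' log-hazard slope per unit within its segment.  The encoding object
#' collects the spline knots, the centering constants, and the structural
#' choice of which postnatal-age quantity multiplies the interaction terms.
#'
#' @param t_knots numeric(2), postnatal-age knots in weeks (default `c(8, 12)`).
#' @param ga_knot GA knot in weeks (default 27).
#' @param bwsds_knot BWSDS knot in SD units (default -1).
#' @param c_ga_main centering constant subtracted from the lower GA basis
#'   (main effect and its postnatal-age interaction); default 28.
#' @param c_ga_sex centering constant for GA inside the sex-by-GA product;
#'   default 28.
#' @param c_bwsds centering constant subtracted from the lower BWSDS basis;
#'   default 0.
#' @param t_interaction_form `"raw"` (interactions multiply postnatal age
#'   itself) or `"first_segment"` (they multiply `min(t, t_knots[1])`).
#'
#' @return An object of class `digirop_encoding`.
#' @export
digirop_encoding <- function(t_knots = c(8, 12), ga_knot = 27, bwsds_knot = -1,
                             c_ga_main = 28, c_ga_sex = 28, c_bwsds = 0,
                             t_interaction_form = c("raw", "first_segment")) {
  t_interaction_form <- match.arg(t_interaction_form)
  stopifnot(length(t_knots) == 2L, t_knots[1] > 0, t_knots[2] > t_knots[1],
            is.finite(ga_knot), is.finite(bwsds_knot),
            is.finite(c_ga_main), is.finite(c_ga_sex), is.finite(c_bwsds))
  structure(list(t_knots = as.numeric(t_knots), ga_knot = as.numeric(ga_knot),
                 bwsds_knot = as.numeric(bwsds_knot),
                 c_ga_main = as.numeric(c_ga_main),
                 c_ga_sex = as.numeric(c_ga_sex),
                 c_bwsds = as.numeric(c_bwsds),
                 t_interaction_form = t_interaction_form),
            class = "digirop_encoding")
}

#' @export
print.digirop_encoding <- function(x, ...) {
  cat("DIGIROP basis encoding\n")
  cat(sprintf("  postnatal-age knots : %g, %g weeks\n", x$t_knots[1], x$t_knots[2]))
  cat(sprintf("  GA knot             : %g weeks (centered at %g; sex-by-GA at %g)\n",
              x$ga_knot, x$c_ga_main, x$c_ga_sex))
  cat(sprintf("  BWSDS knot          : %g SDS (centered at %g)\n",
              x$bwsds_knot, x$c_bwsds))
  cat(sprintf("  interaction time    : %s\n", x$t_interaction_form))
  invisible(x)
}

# canonical order of the 14 design-row components (matches the published
# coefficient table top to bottom)
digirop_term_names <- function() {
  c("intercept",
    "t_0_8", "t_8_12", "t_gt12",
    "ga_24_27", "ga_gt27",
    "sex",
    "bwsds_le_m1", "bwsds_gt_m1",
    "t_x_ga_24_27", "t_x_ga_gt27",
    "sex_x_ga",
    "t_x_bwsds_le_m1", "t_x_bwsds_gt_m1")
}

# covariate (time-free) basis pieces; each argument may be a vector
.ga_basis <- function(ga, enc) {
  list(lo = pmin(ga, enc$ga_knot) - enc$c_ga_main,
       hi = pmax(ga - enc$ga_knot, 0))
}

.bwsds_basis <- function(bwsds, enc) {
  list(lo = pmin(bwsds, enc$bwsds_knot) - enc$c_bwsds,
       hi = pmax(bwsds - enc$bwsds_knot, 0))
}

# segment-slope basis in t: (min(t,k1), clamp(t-k1, 0, k2-k1), max(t-k2, 0))
.t_basis <- function(t, enc) {
  k1 <- enc$t_knots[1]; k2 <- enc$t_knots[2]
  cbind(pmin(t, k1), pmax(pmin(t - k1, k2 - k1), 0), pmax(t - k2, 0))
}

# the postnatal-age quantity entering interaction products
.t_interaction <- function(t, enc) {
  if (enc$t_interaction_form == "raw") t else pmin(t, enc$t_knots[1])
}

#' Design row(s) for the hazard model
#'
#' Builds the 14-component design row whose inner product with the
#' coefficient vector is the log hazard (events per week, log scale) at
#' postnatal age `t`.
#'
#' @param infants data frame with columns `ga_weeks`, `sex` (codes 1 = boy,
#'   2 = girl), `bwsds`; see [infant()].
#' @param t postnatal age(s) in weeks, non-negative.  Either a scalar
#'   (applied to all infants) or a vector of `nrow(infants)` ages.
#' @param encoding a [digirop_encoding()].
#'
#' @return numeric matrix, `nrow(infants)` x 14.
#' @export
design_row <- function(infants, t, encoding = digirop_encoding()) {
  infants <- validate_infants(infants)
  if (any(!is.finite(t)) || any(t < 0))
    stop("postnatal age 't' must be finite and non-negative", call. = FALSE)
  n <- nrow(infants)
  if (n == 1L && length(t) > 1L) {
    # one infant, many ages: evaluate along the time grid
    infants <- infants[rep(1L, length(t)), , drop = FALSE]
    n <- length(t)
  }
  if (length(t) == 1L) t <- rep(t, n)
  if (length(t) != n)
    stop("'t' must be a scalar or one age per infant", call. = FALSE)

  ga <- .ga_basis(infants$ga_weeks, encoding)
  bw <- .bwsds_basis(infants$bwsds, encoding)
  tb <- .t_basis(t, encoding)
  ti <- .t_interaction(t, encoding)
  X <- cbind(1, tb,
             ga$lo, ga$hi,
             infants$sex,
             bw$lo, bw$hi,
             ti * ga$lo, ti * ga$hi,
             infants$sex * (infants$ga_weeks - encoding$c_ga_sex),
             ti * bw$lo, ti * bw$hi)
  colnames(X) <- digirop_term_names()
  X
}
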