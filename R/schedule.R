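#' Suggested postnatal age at first ROP examination
#'
#' The schedule rule: the suggested first-examination age for a GA stratum
#' is the integer part of the earliest observed age at ROP treatment in
#' that stratum, minus 1 week for safety.
#'
#' @param min_treatment_age earliest observed treatment age(s), weeks; must
#'   exceed 1.
#' @return integer week(s): `floor(min_treatment_age) - 1`.
#' @examples
#' suggested_first_exam(c(8.3, 7.4, 7.0, 7.9, 7.6, 8.0))  # 7 6 6 6 6 7
#' @export
suggested_first_exam <- function(min_treatment_age) {
  if (any(!is.finite(min_treatment_age) | min_treatment_age <= 1))
    stop("min_treatment_age must be finite and > 1 week", call. = FALSE)
  as.integer(floor(min_treatment_age) - 1)
}

#' Latest age at which cumulative risk stays below a threshold
#'
#' For a population (typically one GA stratum with its empirical sex and
#' BWSDS mix), finds the largest postnatal age on a 0.1-week grid at which
#' the population-averaged cumulative risk is still below the threshold.
#' With `average = "per_infant"` the age is computed for each infant and
#' the minimum returned (most conservative infant).
#'
#' @param population data frame of infant covariates (`ga_weeks`, `sex`,
#'   `bwsds`).
#' @param model a `digirop` model.
#' @param threshold risk threshold, default 0.001.
#' @param horizon search horizon, default 20 weeks.
#' @param step grid resolution in weeks, default 0.1.
#' @param average `"population"` (mean risk, default) or `"per_infant"`.
#' @return age in weeks; carries attribute `reached = FALSE` when the
#'   threshold is never crossed by the horizon (the horizon is returned).
#' @export
risk_threshold_age <- function(population, model = digirop_model(),
                               threshold = 0.001, horizon = 20, step = 0.1,
                               average = c("population", "per_infant")) {
  average <- match.arg(average)
  population <- validate_infants(population)
  if (!nrow(population)) stop("empty population", call. = FALSE)
  grid <- seq(0, horizon, by = step)
  meanF <- vapply(grid, function(tt) {
    F <- cumulative_risk(population, tt, model, horizon)
    if (average == "population") mean(F) else max(F)
  }, numeric(1))
  below <- meanF < threshold
  if (all(below)) {
    out <- horizon
    attr(out, "reached") <- FALSE
    return(out)
  }
  out <- grid[max(which(below))]
  attr(out, "reached") <- TRUE
  out
}

#' Avoided-visit accounting for a revised screening start
#'
#' Counts weekly screening visits from a per-GA start age to each infant's
#' screening end under an old and a new schedule; visits saved by starting
#' later are "avoided".  A new start earlier than the old one never counts
#' negatively.
#'
#' @param cohort cohort data frame; screening end per infant is
#'   `time_weeks`.
#' @param old_start,new_start named numeric vectors of start ages (weeks)
#'   keyed by completed GA week; every GA stratum present in the cohort
#'   must be covered.
#' @return list `avoided`, `total` (visits under the old schedule),
#'   `fraction`.
#' @examples
#' co <- data.frame(id = 1, ga_weeks = 27, sex = 1, bwsds = 0,
#'                  event = 0, time_weeks = 14)
#' avoided_visits(co, old_start = c("27" = 4), new_start = c("27" = 6))
#' @export
avoided_visits <- function(cohort, old_start, new_start) {
  cohort <- validate_cohort(cohort)
  ga_wk <- as.character(floor(cohort$ga_weeks))
  miss <- setdiff(unique(ga_wk), union(names(old_start), character(0)))
  if (length(miss) || !all(unique(ga_wk) %in% names(new_start)))
    stop("start ages missing for GA week(s): ",
         paste(union(miss, setdiff(unique(ga_wk), names(new_start))),
               collapse = ", "), call. = FALSE)
  old <- unname(old_start[ga_wk])
  new <- unname(new_start[ga_wk])
  end <- cohort$time_weeks
  total <- sum(pmax(end - pmin(old, end), 0))
  avoided <- sum(pmax(pmin(new, end) - pmin(old, end), 0))
  list(avoided = avoided, total = total,
       fraction = if (total > 0) avoided / total else 0)
}

#' Screening-schedule table for a cohort
#'
#' Per completed GA week: the observed minimum treatment age, the suggested
#' first-examination age (postnatal and postmenstrual), and the latest age
#' at which the stratum's population-averaged cumulative risk is below the
#' threshold.
#'
#' @param cohort cohort data frame.
#' @param model a `digirop` model.
#' @param threshold risk threshold for [risk_threshold_age()].
#' @return data frame, one row per GA week present.
#' @export
schedule_table <- function(cohort, model = digirop_model(),
                           threshold = 0.001) {
  cohort <- validate_cohort(cohort)
  ga_wk <- floor(cohort$ga_weeks)
  out <- lapply(sort(unique(ga_wk)), function(g) {
    strat <- cohort[ga_wk == g, , drop = FALSE]
    treated <- strat[strat$event == 1L, , drop = FALSE]
    min_age <- if (nrow(treated)) min(treated$time_weeks) else NA_real_
    sugg <- if (!is.na(min_age) && min_age > 1)
      suggested_first_exam(min_age) else NA_integer_
    thr <- risk_threshold_age(strat[, c("ga_weeks", "sex", "bwsds")],
                              model, threshold)
    data.frame(ga_week = g, n = nrow(strat), n_treated = nrow(treated),
               min_treatment_age = min_age,
               suggested_first_exam_postnatal = sugg,
               suggested_first_exam_postmenstrual = sugg + g,
               risk_threshold_age = as.numeric(thr),
               threshold_reached = isTRUE(attr(thr, "reached")))
  })
  do.call(rbind, out)
}
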