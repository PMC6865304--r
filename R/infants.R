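#' Construct and validate infant covariate records
#'
#' The model uses three predictors measured at birth: continuous gestational
#' age (GA) in weeks, sex coded numerically (1 = boy, 2 = girl), and the
#' birth-weight SD score (BWSDS), i.e. birth weight standardized against a
#' sex- and GA-specific population reference.  BWSDS is an input here; it is
#' not computed from raw grams.
#'
#' @param ga_weeks gestational age in decimal weeks, or a "weeks+days" string
#'   such as `"24+3"` (see [parse_ga()]).  Supported range is 24 to <31 weeks.
#' @param sex `"boy"`/`"girl"` (also accepts `"male"`/`"female"`, 1, 2).
#' @param bwsds birth-weight SD score, dimensionless.
#' @param birth_weight_g optional birth weight in grams (informational only).
#'
#' @return One-row data frame with columns `ga_weeks`, `sex`, `bwsds` (and
#'   `birth_weight_g` when given).
#' @examples
#' infant("24+3", "girl", bwsds = -1.5)
#' @export
infant <- function(ga_weeks, sex, bwsds, birth_weight_g = NULL) {
  if (is.character(ga_weeks)) ga_weeks <- parse_ga(ga_weeks)
  d <- data.frame(ga_weeks = ga_weeks, sex = normalize_sex(sex), bwsds = bwsds)
  if (!is.null(birth_weight_g)) d$birth_weight_g <- birth_weight_g
  validate_infants(d)
}

#' Normalize sex labels to the model's numeric codes
#'
#' @param sex vector of labels: `"boy"`, `"girl"`, `"male"`, `"female"`,
#'   `"m"`, `"f"`, or the codes 1/2 themselves.
#' @return integer vector of codes (1 = boy, 2 = girl).
#' @export
normalize_sex <- function(sex) {
  if (is.numeric(sex)) {
    out <- as.integer(sex)
  } else {
    key <- tolower(trimws(as.character(sex)))
    map <- c(boy = 1L, male = 1L, m = 1L, "1" = 1L,
             girl = 2L, female = 2L, f = 2L, "2" = 2L)
    out <- unname(map[key])
  }
  if (any(is.na(out)) || !all(out %in% c(1L, 2L)))
    stop("sex must be boy/girl (codes 1/2); got: ",
         paste(unique(sex[!(out %in% c(1L, 2L)) | is.na(out)]), collapse = ", "),
         call. = FALSE)
  out
}

# internal validation shared by every entry point taking infant covariates
validate_infants <- function(infants, ga_range = c(24, 31)) {
  if (!is.data.frame(infants))
    stop("infant covariates must be a data frame (see infant())", call. = FALSE)
  need <- c("ga_weeks", "sex", "bwsds")
  miss <- setdiff(need, names(infants))
  if (length(miss))
    stop("missing infant columns: ", paste(miss, collapse = ", "), call. = FALSE)
  infants$sex <- normalize_sex(infants$sex)
  if (any(!is.finite(infants$ga_weeks)))
    stop("ga_weeks must be finite", call. = FALSE)
  if (any(infants$ga_weeks < ga_range[1] | infants$ga_weeks >= ga_range[2]))
    stop(sprintf("ga_weeks outside the supported range [%g, %g)",
                 ga_range[1], ga_range[2]), call. = FALSE)
  if (any(!is.finite(infants$bwsds)))
    stop("bwsds must be finite", call. = FALSE)
  infants
}

#' Parse gestational age given as weeks+days
#'
#' Clinical GA is reported in completed weeks plus days; `"24+3"` means 24
#' weeks and 3 days, i.e. 24 + 3/7 decimal weeks.  Plain decimal strings are
#' accepted unchanged.
#'
#' @param text character vector like `"24+3"` or `"24.43"`.
#' @return numeric decimal weeks.
#' @examples
#' parse_ga("24+3")   # 24.428...
#' parse_ga("30+6")
#' @export
parse_ga <- function(text) {
  one <- function(s) {
    s <- trimws(s)
    if (grepl("^[0-9]+\\+[0-9]+$", s)) {
      parts <- as.numeric(strsplit(s, "+", fixed = TRUE)[[1]])
      if (parts[2] >= 7)
        stop("days part of GA must be 0-6 in '", s, "'", call. = FALSE)
      parts[1] + parts[2] / 7
    } else if (grepl("^[0-9]*\\.?[0-9]+$", s)) {
      as.numeric(s)
    } else {
      stop("cannot parse GA token '", s, "' (expected 'weeks+days' or decimal)",
           call. = FALSE)
    }
  }
  vapply(text, one, numeric(1), USE.NAMES = FALSE)
}

#' Format decimal weeks as weeks+days
#' @param ga_weeks numeric decimal weeks.
#' @return character like `"24+3"` (days rounded to nearest integer).
#' @export
format_ga <- function(ga_weeks) {
  w <- floor(ga_weeks)
  d <- round((ga_weeks - w) * 7)
  w <- w + (d == 7)
  d <- d %% 7
  sprintf("%d+%d", w, d)
}
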