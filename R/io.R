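#' Read a coefficient file into a digirop model
#'
#' Coefficient files are JSON with fields `names` (14 labels), `estimates`,
#' `ses`, optional `covariance` (14x14), and an `encoding` block.  The
#' packaged fixture (`system.file("extdata",
#' "digirop_birth_coefficients.json", package = "digirop")`) carries the
#' published coefficient set verbatim with the calibrated encoding.
#'
#' @param path file path.
#' @return a `digirop` model.
#' @export
read_coefficients <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("names", "estimates", "ses")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("coefficient file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(j$estimates) != 14L || length(j$ses) != 14L ||
      length(j$names) != 14L)
    stop("coefficient file must carry exactly 14 parameters", call. = FALSE)
  if (!identical(as.character(j$names), digirop_term_names()))
    stop("coefficient names do not match the expected ordering", call. = FALSE)
  if (any(!is.finite(j$estimates)) || any(!is.finite(j$ses)))
    stop("estimates/ses contain non-finite values", call. = FALSE)
  covv <- NULL
  if (!is.null(j$covariance)) {
    covv <- as.matrix(j$covariance)
    if (isTRUE(j$covariance_synthetic)) attr(covv, "synthetic") <- TRUE
  }
  enc <- if (!is.null(j$encoding)) {
    e <- j$encoding
    digirop_encoding(t_knots = e$t_knots, ga_knot = e$ga_knot,
                     bwsds_knot = e$bwsds_knot, c_ga_main = e$c_ga_main,
                     c_ga_sex = e$c_ga_sex, c_bwsds = e$c_bwsds,
                     t_interaction_form = e$t_interaction_form)
  } else digirop_encoding()
  new_digirop(j$estimates, j$ses, covv, enc)
}

#' Write a digirop model to a coefficient file
#' @param model a `digirop` model.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(model, path) {
  enc <- model$encoding
  j <- list(names = digirop_term_names(),
            estimates = unname(model$estimates),
            ses = unname(model$ses),
            covariance = if (!is.null(model$covariance))
              unname(apply(model$covariance, 1, as.numeric, simplify = FALSE)),
            covariance_synthetic = isTRUE(attr(model$covariance, "synthetic")),
            encoding = list(t_knots = enc$t_knots, ga_knot = enc$ga_knot,
                            bwsds_knot = enc$bwsds_knot,
                            c_ga_main = enc$c_ga_main,
                            c_ga_sex = enc$c_ga_sex, c_bwsds = enc$c_bwsds,
                            t_interaction_form = enc$t_interaction_form))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Expected columns: `id`, `ga_weeks` (decimal weeks) or the pair
#' `ga_weeks` + `ga_days` (completed weeks and days), `sex`, `bwsds`,
#' `treated` (0/1; accepted alias `event`), `time_weeks`.  Schema problems
#' are reported with the offending line numbers.
#'
#' @param path file path.
#' @return validated cohort data frame with the internal schema
#'   (`event` column, decimal `ga_weeks`).
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("ga_days" %in% names(d)) {
    if (any(d$ga_days < 0 | d$ga_days >= 7, na.rm = TRUE))
      stop("ga_days must be 0-6; offending line(s): ",
           paste(which(d$ga_days < 0 | d$ga_days >= 7) + 1L, collapse = ", "),
           call. = FALSE)
    d$ga_weeks <- d$ga_weeks + d$ga_days / 7
    d$ga_days <- NULL
  }
  if ("treated" %in% names(d) && !"event" %in% names(d)) {
    d$event <- d$treated
    d$treated <- NULL
  }
  need <- c("id", "ga_weeks", "sex", "bwsds", "event", "time_weeks")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!d$event %in% c(0, 1))
  if (length(bad))
    stop("event/treated must be 0/1; offending line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$time_weeks) | d$time_weeks <= 0)
  if (length(bad))
    stop("time_weeks must be positive; offending line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  validate_cohort(d[, need])
}

#' Write a cohort CSV in the package schema
#' @param cohort cohort data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  names(cohort)[names(cohort) == "event"] <- "treated"
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a risk curve to CSV or JSON
#' @param curve a `digirop_risk` data frame.
#' @param path destination; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_risk_curve <- function(curve, path) {
  d <- as.data.frame(curve)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a run manifest alongside an output file
#'
#' Records inputs, seed, package version and a hash of the configuration so
#' two runs with equal manifests are byte-reproducible.
#'
#' @param out_path the output the manifest describes; the manifest lands at
#'   `<out_path>.manifest.json`.
#' @param command name of the operation.
#' @param config named list of inputs/settings (seed included).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(out_path, command, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command, output = out_path, config = config,
                   config_hash = sum(utf8ToInt(as.character(cfg_json))),
                   package_version = as.character(utils::packageVersion("digirop")),
                   r_version = R.version.string)
  mp <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
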