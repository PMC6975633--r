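# Readers for the two bundled plain-text inputs and a report writer
# mirroring the published result tables.

#' Path to a bundled data file
#'
#' @param file file name under the package's `extdata/`; with no
#'   argument, lists the bundled files. Bundled inputs:
#'   `flight_table1.csv` (the published femoral-neck flight
#'   observations), `table3_tscores.csv` (the published T-score grid),
#'   and `reference_groups_synthetic.csv` (synthetic group mean
#'   pre-mission BMDs, back-derived from the published 400-day T-score
#'   column — not genuine NHANES values).
#' @return absolute path, or a vector of file names.
#' @export
marsbmd_extdata <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "marsbmd")))
  p <- system.file("extdata", file, package = "marsbmd")
  if (p == "") stop("no bundled file called '", file, "'")
  p
}

#' Read a flight-observation table
#'
#' CSV with header
#' `duration_days,duration_sd_days,bmd_change_pct,dispersion_pct,n,source`
#' (UTF-8, dot decimal). BMD changes are printed as negative percent
#' changes and are negated on ingest into positive losses; blank
#' optional cells become `NA`; row order is preserved.
#'
#' @param path CSV file path.
#' @return data.frame of flight observations: `duration_days`,
#'   `duration_sd_days`, `loss_pct`, `dispersion_pct`, `n_astronauts`,
#'   `source_label`.
#' @examples
#' obs <- read_flight_table(marsbmd_extdata("flight_table1.csv"))
#' sum(obs$n_astronauts)  # 138 row-weight total
#' @export
read_flight_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("duration_days", "duration_sd_days", "bmd_change_pct",
            "dispersion_pct", "n", "source")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("flight table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("duration_days", "duration_sd_days", "bmd_change_pct",
                "dispersion_pct", "n")) {
    v <- raw[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at data row ", bad[1])
      raw[[col]] <- conv
    }
  }
  if (nrow(raw)) {
    if (anyNA(raw$duration_days) || any(raw$duration_days <= 0))
      stop("duration_days must be present and positive")
    if (anyNA(raw$n) || any(raw$n < 1))
      stop("astronaut count 'n' must be present and >= 1")
  }
  data.frame(duration_days = raw$duration_days,
             duration_sd_days = raw$duration_sd_days,
             loss_pct = -raw$bmd_change_pct,
             dispersion_pct = raw$dispersion_pct,
             n_astronauts = as.integer(raw$n),
             source_label = raw$source,
             stringsAsFactors = FALSE)
}

#' Read a reference-group table
#'
#' CSV with header `sex,ethnicity,age_min,age_max,premission_bmd_g_cm2`.
#' Groups must be unique by (sex, ethnicity, age band) and BMDs must be
#' plausible femoral-neck values (0.4-1.5 g/cm2).
#'
#' @param path CSV file path.
#' @return data.frame of reference groups.
#' @export
read_reference_groups <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "ethnicity", "age_min", "age_max", "premission_bmd_g_cm2")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(g)) {
    key <- interaction(g$sex, g$ethnicity, g$age_min, drop = TRUE)
    if (anyDuplicated(key)) stop("duplicate reference group")
    if (any(!is.finite(g$premission_bmd_g_cm2)) ||
        any(g$premission_bmd_g_cm2 <= 0.4 | g$premission_bmd_g_cm2 >= 1.5))
      stop("premission_bmd_g_cm2 outside the plausible range (0.4, 1.5)")
  }
  g
}

#' Write an analysis report
#'
#' Collects the fitted rate and kinetics, per-duration predicted
#' losses, the assessment grid and scenario summaries into one report.
#' `format = "json"` writes a single JSON file that round-trips
#' losslessly through [read_report()]; `format = "csv"` writes
#' `<stem>_fit.csv`, `<stem>_assessments.csv` and `<stem>_summary.csv`
#' next to `path`.
#'
#' @param fit a converged `decay_fit`.
#' @param assessments output of [assess_mission()], or `NULL`.
#' @param summaries list of [summarize_classifications()] results, or
#'   `NULL`.
#' @param path output file (JSON) or stem (CSV).
#' @param format `"json"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(fit, assessments = NULL, summaries = NULL,
                         path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(fit, "decay_fit"))
  kin <- derive_kinetics(as_decay_model(fit))
  rep_fit <- list(lambda_per_day = fit$lambda_hat,
                  se_lambda = fit$se_lambda,
                  ci95 = as.numeric(fit$ci95),
                  half_life_days = kin$half_life_days,
                  time_constant_days = kin$time_constant_days,
                  plateau_pct = fit$plateau_pct,
                  weighting = fit$weighting,
                  n_rows = fit$n_rows, total_n = fit$total_n)
  if (format == "json") {
    report <- list(kinetics = rep_fit)
    if (!is.null(assessments)) {
      a <- assessments
      a$who_class <- as.character(a$who_class)
      report$assessments <- a
    }
    if (!is.null(summaries)) report$summaries <- summaries
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  paths <- paste0(stem, "_fit.csv")
  utils::write.csv(as.data.frame(rep_fit[c("lambda_per_day", "se_lambda",
                                           "half_life_days",
                                           "time_constant_days",
                                           "plateau_pct")]),
                   paths[1], row.names = FALSE)
  if (!is.null(assessments)) {
    p <- paste0(stem, "_assessments.csv")
    utils::write.csv(assessments, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(summaries)) {
    p <- paste0(stem, "_summary.csv")
    utils::write.csv(do.call(rbind, lapply(summaries, as.data.frame)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
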