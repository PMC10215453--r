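# Summary statistics, the reference per-ear measurements of the original
# cadaver series, and report aggregation / serialization.

#' Mean and sample standard deviation
#'
#' Arithmetic mean and sample SD (n - 1 denominator, the convention that
#' reproduces the printed dispersion values of the reference cadaver
#' tables). Rounding to a table's printed precision happens at report time
#' only.
#'
#' @param values numeric vector; at least 1 value for the mean, at least 2
#'   for the SD (otherwise the SD is `NA`).
#' @return Named numeric `c(mean = , sd = )`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("cannot summarize an empty list of values")
  if (any(!is.finite(values))) stop("values must be finite")
  c(mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}

#' Reference per-ear measurements of the cadaver series
#'
#' The per-ear measurements reported for the five cadaver ears on which
#' this quantification method was developed: percent increases in
#' air-density pixels for the three ROI boxes, percent increases in lumen
#' width at the three levels, and the three straight-line lumen lengths in
#' pixels.
#'
#' @return List of three data frames: `air_increase` (percent, integers),
#'   `width_increase` (percent), `distances_px` (pixels).
#' @export
reference_measurements <- function() {
  list(
    air_increase = data.frame(
      ear = 1:5,
      small = c(20, 33, 68, 100, 98),
      longest = c(6, 23, 50, 74, 68),
      long = c(8, 26, 62, 97, 88)),
    width_increase = data.frame(
      ear = 1:5,
      np = c(3.5, 0, 9, 4.2, 25),
      mid = c(57.8, 93.5, 75.6, 53.3, 78.9),
      isthmus = c(31.6, 10, 100, 47.2, 0)),
    distances_px = data.frame(
      ear = 1:5,
      total = c(67.99, 87.74, 73.37, 75.41, 72.6),
      torus_to_widest = c(50.45, 56.01, 44.24, 37.79, 37.79),
      widest_to_tip = c(20.82, 34.41, 30.16, 38.09, 32.82)))
}

#' Summary rows of the reference measurements
#'
#' Applies [summarize_values()] to every column of the reference per-ear
#' tables and rounds to each table's printed precision: air-increase means
#' to integers, width means/SDs to one decimal, distance means to two
#' decimals and SDs to one.
#'
#' @return Data frame with columns `table`, `column`, `mean`, `sd`.
#' @export
summarize_reference <- function() {
  ref <- reference_measurements()
  spec <- list(
    air_increase = list(cols = c("small", "longest", "long"),
                        mean_digits = 0, sd_digits = NA),
    width_increase = list(cols = c("np", "mid", "isthmus"),
                          mean_digits = 1, sd_digits = 1),
    distances_px = list(cols = c("total", "torus_to_widest",
                                 "widest_to_tip"),
                        mean_digits = 2, sd_digits = 1))
  out <- do.call(rbind, lapply(names(spec), function(tab) {
    s <- spec[[tab]]
    do.call(rbind, lapply(s$cols, function(cl) {
      st <- summarize_values(ref[[tab]][[cl]])
      data.frame(table = tab, column = cl,
                 mean = round_half_up(st[["mean"]] * 10^s$mean_digits) /
                   10^s$mean_digits,
                 sd = if (is.na(s$sd_digits)) NA_real_ else
                   round_half_up(st[["sd"]] * 10^s$sd_digits) /
                     10^s$sd_digits)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Dilation report container
#'
#' Aggregates per-ear quantification records and their column-wise summary
#' (mean and sample SD over ears).
#'
#' @param per_ear data frame of per-ear records (one row per ear, first
#'   column `ear_id`).
#' @param config the configuration the report was produced from.
#' @param air_mode headline air-counting mode.
#' @return An object of class `dilation_report`.
#' @export
dilation_report <- function(per_ear, config = NULL, air_mode = "partial") {
  if (!is.data.frame(per_ear) || !nrow(per_ear))
    stop("'per_ear' must be a non-empty data frame")
  num_cols <- names(per_ear)[vapply(per_ear, is.numeric, logical(1))]
  summary <- do.call(rbind, lapply(num_cols, function(cl) {
    vals <- per_ear[[cl]]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) return(NULL)
    st <- summarize_values(vals)
    data.frame(column = cl, mean = st[["mean"]], sd = st[["sd"]], n = length(vals))
  }))
  rownames(summary) <- NULL
  structure(list(per_ear = per_ear, summary = summary,
                 air_mode = air_mode, config = config),
            class = "dilation_report")
}

#' @export
print.dilation_report <- function(x, ...) {
  cat(sprintf("dilation report: %d ears, headline air mode '%s'\n",
              nrow(x$per_ear), x$air_mode))
  pct_cols <- grep("^pct_.*_partial$", names(x$per_ear), value = TRUE)
  if (length(pct_cols)) {
    cat("percent increase in air pixels (partial mode):\n")
    tab <- x$per_ear[, c("ear_id", pct_cols)]
    tab[pct_cols] <- lapply(tab[pct_cols], round, digits = 1)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Write a dilation report
#'
#' Writes `per_ear.csv` and `summary.csv` (human-readable tables) and
#' `report.json` (lossless full-precision records plus configuration and
#' headline mode) into a directory.
#'
#' @param report a [dilation_report()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "dilation_report")) stop("not a dilation_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_ear, file.path(dir, "per_ear.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(air_mode = report$air_mode, per_ear = report$per_ear,
         summary = report$summary, config = report$config),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a dilation report written by [write_report()]
#' @param dir report directory.
#' @return A [dilation_report()].
#' @export
read_report <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  dilation_report(as.data.frame(obj$per_ear), config = obj$config,
                  air_mode = obj$air_mode)
}
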