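#' @include synthetic.R
NULL

#' Year correction offsets from benchmark birds
#'
#' The benchmark is the set of returning ASY birds captured at the focal
#' (known-origin) area: their delta-2H mean in the benchmark year defines the
#' reference, and every other year's offset is
#' `mean(benchmark year) - mean(year y)` — the amount *added* to year-`y`
#' values to bring them onto the benchmark-year scale. The benchmark year's
#' own offset is exactly 0. Offsets are displayed rounded to 0.1 per mil but
#' carried at full precision.
#'
#' @param records benchmark-area records (data.frame with `year` and `d2H`),
#'   or `NULL` when `means` is supplied.
#' @param benchmarkYear the reference year.
#' @param means optional named numeric of per-year delta-2H means, used
#'   instead of raw records (e.g. published summary values).
#' @return object of class `"YearCorrection"`: list with `benchmarkYear`,
#'   `offsets` (named per-year, benchmark included at 0) and `means`.
#' @examples
#' yc <- yearOffsets(means = c("2010" = -67.0, "2011" = -88.1,
#'                             "2012" = -78.9), benchmarkYear = 2010)
#' yc$offsets
#' @export
yearOffsets <- function(records = NULL, benchmarkYear, means = NULL) {
  if (is.null(means)) {
    stopifnot(all(c("year", "d2H") %in% names(records)))
    ok <- is.finite(records$d2H)
    counts <- table(records$year[ok])
    if (any(counts < 2))
      stop("year(s) with < 2 benchmark birds: ",
           paste(names(counts)[counts < 2], collapse = ", "))
    means <- tapply(records$d2H[ok], records$year[ok], mean)
  }
  means <- stats::setNames(as.numeric(means), names(means))
  by <- as.character(benchmarkYear)
  if (!by %in% names(means))
    stop("benchmark year ", benchmarkYear, " absent from the benchmark data")
  offsets <- means[by] - means
  structure(list(benchmarkYear = as.integer(benchmarkYear),
                 offsets = offsets, means = means),
            class = "YearCorrection")
}

#' @export
print.YearCorrection <- function(x, ...) {
  cat(sprintf("YearCorrection (benchmark %d):\n", x$benchmarkYear))
  for (y in names(x$offsets))
    cat(sprintf("  %s: %+.1f per mil\n", y, x$offsets[[y]]))
  invisible(x)
}

#' Apply year and age corrections to delta-2H
#'
#' ASY records from non-benchmark years receive the year offset; SY records
#' receive the age correction factor. delta-34S is never calibrated. The
#' returned records carry an `"audit"` attribute logging, per record, the raw
#' value, each offset applied and the final value.
#'
#' @param records record data.frame with `year`, `age`, `d2H`.
#' @param yc a `"YearCorrection"` from [yearOffsets()], or `NULL` to skip
#'   year correction.
#' @param ageFactor per-mil correction added to each SY bird's delta-2H,
#'   one of the sensitivity set `c(-6, -3, 0, 3, 6)` by convention.
#' @param applyYearToSY should SY birds also receive the year offset
#'   (default `FALSE`: SY birds are assigned on the benchmark-year scale and
#'   only age-corrected).
#' @return the records with corrected `d2H` and an `"audit"` attribute.
#' @export
applyCorrections <- function(records, yc = NULL, ageFactor = 0,
                             applyYearToSY = FALSE) {
  stopifnot(all(c("year", "age", "d2H") %in% names(records)))
  yearOff <- rep(0, nrow(records))
  if (!is.null(yc)) {
    yrs <- as.character(records$year)
    missing <- setdiff(unique(yrs), names(yc$offsets))
    if (length(missing))
      stop("year(s) not covered by the year correction: ",
           paste(missing, collapse = ", "))
    yearOff <- unname(yc$offsets[yrs])
    if (!applyYearToSY) yearOff[records$age == "SY"] <- 0
  }
  ageOff <- ifelse(records$age == "SY", ageFactor, 0)
  out <- records
  out$d2H <- records$d2H + yearOff + ageOff
  attr(out, "audit") <- data.frame(
    id = if ("id" %in% names(records)) records$id else seq_len(nrow(records)),
    raw_d2H = records$d2H, year_offset = yearOff, age_offset = ageOff,
    final_d2H = out$d2H, stringsAsFactors = FALSE)
  out
}

#' Pooled-variance two-sample t test for a delta-34S year effect
#'
#' Classical equal-variance two-sample t statistic with
#' `df = n1 + n2 - 2`, computed either from raw value vectors or from
#' `(mean, sd, n)` summaries. Mean differences not exceeding the
#' `measurementError` (the ±2 per-mil within-run precision of the isotope
#' assay) are flagged `negligible` regardless of significance.
#'
#' @param groupA,groupB numeric vectors of raw values, or lists / named
#'   vectors with elements `mean`, `sd`, `n`.
#' @param measurementError per-mil assay precision used for the negligibility
#'   flag (default 2).
#' @return list with `t`, `df`, `p` (two-sided), `meanDiff` (B - A) and
#'   `negligible`.
#' @examples
#' sulfurYearTest(list(mean = 6.79, sd = 0.58, n = 23),
#'                list(mean = 6.30, sd = 0.29, n = 11))
#' @export
sulfurYearTest <- function(groupA, groupB, measurementError = 2) {
  summarize <- function(g) {
    if (is.list(g) || !is.null(names(g)))
      list(mean = as.numeric(g[["mean"]]), sd = as.numeric(g[["sd"]]),
           n = as.numeric(g[["n"]]))
    else list(mean = mean(g), sd = stats::sd(g), n = length(g))
  }
  a <- summarize(groupA); b <- summarize(groupB)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- b$mean - a$mean
  if (sp2 == 0) {
    if (diff != 0)
      stop("degenerate test: zero pooled variance with unequal means")
    return(list(t = 0, df = df, p = 1, meanDiff = 0, negligible = TRUE))
  }
  t <- diff / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), meanDiff = diff,
       negligible = abs(diff) <= measurementError)
}
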