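#' Build a survey table of river sections
#'
#' @param river,section character vectors naming each surveyed section.
#' @param length_km surveyed length per section (km, > 0).
#' @param count birds counted on the section (>= 0).
#' @param source optional provenance per section.
#' @return data.frame of class \code{surveyTable}.
#' @export
surveyTable <- function(river, section, length_km, count, source = NA) {
  if (any(length_km <= 0)) stop("section lengths must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  out <- data.frame(river = river, section = section,
                    length_km = length_km, count = count,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("surveyTable", "data.frame")
  out
}

#' Read a survey table from CSV
#'
#' Expects columns \code{river}, \code{section}, \code{length_km},
#' \code{count} (\code{source} optional).
#' @param file path to a CSV file.
#' @export
readSurveyCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  surveyTable(df$river, df$section, df$length_km, df$count,
              if (is.null(df$source)) NA else df$source)
}

#' Bundled winter survey of eight river sections
#'
#' Line-transect counts of wintering Scaly-sided Mergansers on eight
#' sections of six Yangtze-basin rivers (Li, Yuan, Xiu, Fu, Xin and
#' Rao), from three winters of boat/walking surveys plus two published
#' counts; the worked example in the README reproduces the per-km
#' densities from these lengths and counts.
#'
#' @return A \code{surveyTable} (see [surveyTable()]).
#' @export
mergSurvey <- function() {
  readSurveyCSV(system.file("extdata", "merganser_survey.csv",
                            package = "riverSDM", mustWork = TRUE))
}

# round half away from zero (base round() is round-half-even)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-section densities and their summary
#'
#' Density is count/length (birds per km) per section, reported rounded
#' half-up to \code{decimals}; the summary (mean, sample SD, min, max)
#' uses the unrounded values.
#'
#' @param table a \code{surveyTable}.
#' @param decimals digits for the presented densities (default 2).
#' @return List: \code{densities} (data.frame with unrounded
#'   \code{density} and presented \code{densityRounded}) and
#'   \code{summary} (mean, sd, min, max, n).
#' @export
sectionDensities <- function(table, decimals = 2) {
  d <- table$count / table$length_km
  out <- cbind(as.data.frame(table),
               density = d, densityRounded = roundHalfUp(d, decimals))
  list(densities = out,
       summary = list(mean = mean(d),
                      sd = if (length(d) > 1) stats::sd(d) else NA_real_,
                      min = min(d), max = max(d), n = length(d)))
}

#' Range of per-section densities
#'
#' Minimum and maximum of the rounded per-section densities.
#'
#' @inheritParams sectionDensities
#' @return Numeric vector c(min, max).
#' @export
densityRange <- function(table, decimals = 2) {
  d <- roundHalfUp(table$count / table$length_km, decimals)
  c(min = min(d), max = max(d))
}

#' Extrapolate a population estimate over suitable river length
#'
#' The census extrapolation N = D x L. With the (default) unweighted
#' mean, D is the mean of per-section densities and the spread is
#' SD(D) x L; with the length-weighted pooled method, D is total count
#' over total surveyed length and the spread is the pooled Poisson
#' standard error \eqn{\sqrt{\sum counts}/\sum lengths \times L}.
#' Rounding happens only at presentation.
#'
#' @param table a \code{surveyTable}.
#' @param L suitable river length in km (>= 0).
#' @param method "unweighted-mean" (default) or
#'   "length-weighted-pooled".
#' @return List: \code{N} (birds), \code{spread} (birds), \code{method},
#'   \code{L}, \code{densitySummary}, and \code{both} (N under each
#'   method).
#' @examples
#' estimatePopulation(mergSurvey(), L = 6984)
#' @export
estimatePopulation <- function(table, L,
                               method = c("unweighted-mean",
                                          "length-weighted-pooled")) {
  method <- match.arg(method)
  if (L < 0) stop("L must be non-negative")
  if (!nrow(table)) stop("survey table is empty")
  sd_ <- sectionDensities(table)
  meanN <- sd_$summary$mean * L
  meanSpread <- if (is.na(sd_$summary$sd)) 0 else sd_$summary$sd * L
  pooledD <- sum(table$count) / sum(table$length_km)
  pooledN <- pooledD * L
  pooledSpread <- sqrt(sum(table$count)) / sum(table$length_km) * L
  pick <- method == "unweighted-mean"
  list(N = if (pick) meanN else pooledN,
       spread = if (pick) meanSpread else pooledSpread,
       method = method, L = L, densitySummary = sd_$summary,
       both = list(`unweighted-mean` = c(N = meanN, spread = meanSpread),
                   `length-weighted-pooled` = c(N = pooledN,
                                                spread = pooledSpread)))
}
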