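#' Nearest-rank residual quantile shift
#'
#' The vertical shift that places a percentile curve: the empirical quantile
#' of the fit residuals taken at nearest rank \code{ceiling(q * n)}, so that
#' exactly \code{ceiling(q * n)} residuals lie at or below the shifted curve.
#' A counting rule (rather than an interpolated quantile) is used because a
#' reference band is defined by how many data points it spans.
#'
#' @param residuals numeric vector of fit residuals, kb.
#' @param q quantile level in (0, 1).
#' @return the shift delta_q in kb.
#' @examples
#' residual_quantile_shift(c(-1, -0.5, 0, 0.5, 1), 0.10)
#' @export
residual_quantile_shift <- function(residuals, q) {
  if (length(residuals) == 0L) stop("residuals must be non-empty")
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  sorted <- sort(residuals)
  sorted[ceiling(q * length(sorted))]
}

#' Percentile reference bands by vertical shift of the fitted curve
#'
#' Builds a set of percentile curves from a piecewise fit: each requested
#' level's curve is the fitted regression curve shifted vertically by the
#' nearest-rank residual quantile at that level. All bands are therefore
#' parallel to the median trend, and in-sample the band at level q has
#' exactly \code{ceiling(q * n)} observations at or below it.
#'
#' @param fit a \code{piecewise_fit} from [fit_piecewise()].
#' @param levels quantile levels in (0, 1), default the conventional
#'   reference chart set \code{c(0.01, 0.10, 0.50, 0.90, 0.99)}.
#' @return an object of class \code{"band_set"}: list with \code{fit},
#'   \code{levels} and \code{shifts} (named by level).
#' @examples
#' cohort <- generate_cohort(default_healthy_config(seed = 3))
#' lym <- cohort[cohort$subset == "lymphocytes", ]
#' fit <- fit_piecewise(lym$age_years, lym$mtl_kb)
#' b <- reference_bands(fit)
#' band_value(b, 0.90, age = 50) - band_value(b, 0.10, age = 50)
#' @export
reference_bands <- function(fit, levels = c(0.01, 0.10, 0.50, 0.90, 0.99)) {
  stopifnot(inherits(fit, "piecewise_fit"),
            all(levels > 0), all(levels < 1), !is.unsorted(levels))
  shifts <- vapply(levels, residual_quantile_shift,
                   numeric(1), residuals = fit$residuals)
  names(shifts) <- format(levels)
  structure(list(fit = fit, levels = levels, shifts = shifts),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("Percentile reference bands (vertical shifts, kb):\n")
  print(round(x$shifts, 3))
  invisible(x)
}

#' Evaluate a percentile band at an age
#'
#' @param band a \code{band_set}.
#' @param level one of the band's levels.
#' @param age numeric vector of ages, years.
#' @return band curve value(s) in kb: fitted curve + shift at that level.
#' @export
band_value <- function(band, level, age) {
  stopifnot(inherits(band, "band_set"))
  i <- match(level, band$levels)
  if (is.na(i)) stop("level ", level, " not in band set (have: ",
                     paste(band$levels, collapse = ", "), ")")
  predict(band$fit$params, age) + band$shifts[[i]]
}

#' Fraction of records between two percentile bands
#'
#' Counts records with MTL strictly above the lower band and at or below the
#' upper band. When the bands were built from these same records, this
#' fraction is exactly
#' \code{(ceiling(q_high * n) - ceiling(q_low * n)) / n}
#' (absent residual ties) — the construction spans the desired number of
#' data points by design.
#'
#' @param band a \code{band_set}.
#' @param age,mtl_kb record vectors for one subset.
#' @param level_low,level_high band levels with \code{level_low < level_high}.
#' @return fraction in \code{[0, 1]}.
#' @export
band_coverage <- function(band, age, mtl_kb, level_low = 0.10,
                          level_high = 0.90) {
  stopifnot(level_low < level_high, length(age) == length(mtl_kb))
  i_lo <- match(level_low, band$levels)
  i_hi <- match(level_high, band$levels)
  if (is.na(i_lo) || is.na(i_hi)) stop("levels not in band set")
  # compare residuals against the shifts directly: in-sample the shifts ARE
  # residual order statistics, so the counts are exact
  r <- mtl_kb - predict(band$fit$params, age)
  mean(r > band$shifts[[i_lo]] & r <= band$shifts[[i_hi]])
}

#' Empirical percentile of a sample against the reference distribution
#'
#' Places a measurement on the healthy reference distribution at its age:
#' the percentage of reference residuals at or below the sample's residual
#' from the fitted curve (ties count as covered). Values 0 and 100 indicate
#' a sample outside the span of the reference data and are conventionally
#' reported as "<1st" / ">99th".
#'
#' @param band a \code{band_set} built from a healthy reference cohort.
#' @param age age of the sample, years.
#' @param mtl_kb measured MTL, kb.
#' @return numeric percentile(s) in \code{[0, 100]}.
#' @export
percentile_of_sample <- function(band, age, mtl_kb) {
  stopifnot(inherits(band, "band_set"), length(age) == length(mtl_kb))
  ref <- sort(band$fit$residuals)
  r <- mtl_kb - predict(band$fit$params, age)
  # findInterval on the sorted reference counts residuals <= r
  100 * findInterval(r, ref) / length(ref)
}

#' Format a percentile with extreme-value sentinels
#'
#' @param p numeric percentile(s) in \code{[0, 100]}.
#' @return character: \code{"<1st"} below 1, \code{">99th"} above 99,
#'   otherwise the rounded percentile.
#' @export
format_percentile <- function(p) {
  ifelse(p < 1, "<1st", ifelse(p > 99, ">99th", sprintf("%.0fth", p)))
}
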