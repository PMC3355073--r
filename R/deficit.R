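#' Age-adjusted telomere deficit (delta-tel)
#'
#' The difference between a measured median telomere length and the healthy
#' reference regression estimate at the same age. Deficits are negative:
#' a carrier 3 kb below the age-expected trend has delta_tel = -3.
#'
#' @param mtl_kb measured MTL, kb.
#' @param age age in years.
#' @param params healthy-reference \code{piecewise_params}.
#' @return delta-tel in kb, \code{mtl_kb - predict(params, age)}.
#' @examples
#' p <- piecewise_params(11.2, c(-1.190, -0.126, -0.043))
#' delta_tel(5.0, 40, p)
#' @export
delta_tel <- function(mtl_kb, age, params) {
  stopifnot(inherits(params, "piecewise_params"))
  mtl_kb - predict(params, age)
}

#' Mean age-adjusted deficit of a cohort group in one subset
#'
#' @param cohort a \code{cohort_table} (long format).
#' @param params_by_subset named list of healthy-reference
#'   \code{piecewise_params}, one per subset.
#' @param group group label to summarise.
#' @param subset subset label.
#' @return list with \code{mean_delta_kb}, \code{n} and \code{sd_kb}.
#' @examples
#' cfg <- default_affected_config(seed = 11)
#' carriers <- generate_cohort(cfg, c(carrier_TERT = 37, carrier_TERC = 23))
#' # against the configured (true) healthy trends:
#' group_mean_delta(carriers, cfg$subset_params,
#'                  "carrier_TERT", "granulocytes")
#' @export
group_mean_delta <- function(cohort, params_by_subset, group, subset) {
  subset <- canonical_subset(subset)
  rec <- cohort[cohort$group %in% group & cohort$subset == subset, ]
  if (nrow(rec) == 0L)
    stop("no records for group(s) [", paste(group, collapse = ", "),
         "] in subset '", subset, "'")
  p <- params_by_subset[[subset]]
  if (is.null(p)) stop("no reference parameters for subset '", subset, "'")
  d <- delta_tel(rec$mtl_kb, rec$age_years, p)
  list(mean_delta_kb = mean(d), n = nrow(rec), sd_kb = stats::sd(d))
}

#' Screen a cohort against healthy reference bands
#'
#' Computes, for every record, the age-expected MTL from the reference fit,
#' the age-adjusted deficit, the empirical percentile on the reference
#' distribution and a below-1st-percentile flag (MTL strictly below the
#' 1st-percentile band curve at that age) — the screen used to pick out
#' telomerase-mutation carriers, whose telomeres typically sit below the 1st
#' percentile at all ages and in all subsets. Ages beyond the reference
#' range are extrapolated on the adult segment with a warning.
#'
#' @param cohort a \code{cohort_table}.
#' @param bands_by_subset named list of \code{band_set} objects built from a
#'   healthy reference cohort, one per subset present in \code{cohort}. Each
#'   band set must include the 0.01 level for the flag.
#' @return data frame with one row per record: \code{subject_id},
#'   \code{group}, \code{subset}, \code{age_years}, \code{mtl_kb},
#'   \code{expected_kb}, \code{delta_kb}, \code{percentile},
#'   \code{below_first_percentile}.
#' @export
screen_cohort <- function(cohort, bands_by_subset) {
  subsets <- unique(cohort$subset)
  missing <- setdiff(subsets, names(bands_by_subset))
  if (length(missing))
    stop("no reference band for subset(s): ", paste(missing, collapse = ", "))
  out <- lapply(subsets, function(ss) {
    rec <- cohort[cohort$subset == ss, ]
    band <- bands_by_subset[[ss]]
    ref_max <- band$fit$age_range[2]
    if (!is.null(ref_max) && any(rec$age_years > ref_max))
      warning(sum(rec$age_years > ref_max), " record(s) in '", ss,
              "' are older than the reference range (max ", ref_max,
              " yr); extrapolating on the adult segment")
    expected <- predict(band$fit$params, rec$age_years)
    pct <- percentile_of_sample(band, rec$age_years, rec$mtl_kb)
    first <- band_value(band, 0.01, rec$age_years)
    data.frame(subject_id = rec$subject_id,
               group = rec$group,
               subset = ss,
               age_years = rec$age_years,
               mtl_kb = rec$mtl_kb,
               expected_kb = expected,
               delta_kb = rec$mtl_kb - expected,
               percentile = pct,
               below_first_percentile = rec$mtl_kb < first,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise below-1st-percentile flags by group
#'
#' @param screen_result output of [screen_cohort()].
#' @return data frame with the fraction of records flagged per
#'   (group, subset) cell.
#' @export
screen_summary <- function(screen_result) {
  agg <- stats::aggregate(below_first_percentile ~ group + subset,
                          data = screen_result, FUN = mean)
  names(agg)[3] <- "fraction_below_first"
  agg
}
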