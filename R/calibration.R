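#' Calibrate flow-FISH fluorescence to median telomere length
#'
#' Converts background-subtracted telomere-probe fluorescence into kb using
#' an internal control of known telomere length (bovine thymocytes
#' co-processed with each sample):
#' \deqn{MTL = L_{ctrl} \times f \times
#'   \frac{S_{sample} - B_{sample}}{S_{ctrl} - B_{ctrl}}}
#' A sample whose signal does not exceed its unstained background is clamped
#' to 0 kb with a warning. The optional factor \code{f} absorbs any
#' protocol-specific correction between control and sample cells (such as a
#' DNA-ploidy ratio); the default 1 applies no correction.
#'
#' @param sample_signal,sample_background stained / unstained sample
#'   fluorescence, arbitrary units (vectors allowed).
#' @param control_signal,control_background stained / unstained internal
#'   control fluorescence, same units.
#' @param control_length_kb known telomere length of the internal control,
#'   kb. There is no default: it is a property of the control cell batch and
#'   must always be supplied.
#' @param factor multiplicative calibration correction, default 1.
#' @return MTL in kb.
#' @examples
#' mtl_from_fluorescence(500, 20, 980, 20, control_length_kb = 15)  # 7.5
#' @export
mtl_from_fluorescence <- function(sample_signal, sample_background,
                                  control_signal, control_background,
                                  control_length_kb, factor = 1) {
  stopifnot(all(control_length_kb > 0), factor > 0)
  if (any(control_signal <= control_background))
    stop("calibration error: control signal must exceed control background")
  num <- sample_signal - sample_background
  if (any(num < 0)) {
    warning(sum(num < 0),
            " sample(s) with signal below background; reporting 0 kb")
    num <- pmax(num, 0)
  }
  control_length_kb * factor * num / (control_signal - control_background)
}

#' Combine duplicate MTL measurements
#'
#' Duplicate flow-FISH runs of the same sample are combined by arithmetic
#' mean; the record is flagged when the duplicates disagree by more than the
#' tolerance (default 10% of their mean), signalling a measurement that
#' should be repeated.
#'
#' @param values numeric MTL duplicates, kb (at least one).
#' @param tolerance_kb maximum acceptable max-min spread, kb. Default
#'   \code{0.1 * mean(values)}.
#' @return list with \code{mtl_kb} (the mean) and \code{flagged} (logical).
#' @examples
#' merge_duplicates(c(7.0, 7.2), tolerance_kb = 0.5)
#' @export
merge_duplicates <- function(values, tolerance_kb = NULL) {
  if (length(values) == 0L) stop("no duplicate values supplied")
  m <- mean(values)
  if (is.null(tolerance_kb)) tolerance_kb <- 0.1 * m
  list(mtl_kb = m, flagged = (max(values) - min(values)) > tolerance_kb)
}

#' Calibrate a fluorescence table to MTL records
#'
#' Reads a delimited fluorescence table (columns \code{subject_id},
#' \code{subset}, \code{sample_signal}, \code{sample_background},
#' \code{control_signal}, \code{control_background},
#' \code{control_length_kb}; duplicates appear as repeated
#' (subject, subset) rows), converts each row to kb and merges duplicates.
#'
#' @param df data frame with the columns above, or a path to a CSV file.
#' @param tolerance_kb duplicate-agreement tolerance passed to
#'   [merge_duplicates()]; \code{NULL} for the 10%-of-mean default.
#' @return data frame with \code{subject_id}, \code{subset}, \code{mtl_kb},
#'   \code{n_duplicates}, \code{flagged}.
#' @export
calibrate_fluorescence_table <- function(df, tolerance_kb = NULL) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  need <- c("subject_id", "subset", "sample_signal", "sample_background",
            "control_signal", "control_background", "control_length_kb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fluorescence table lacks column(s): ", paste(miss, collapse = ", "))
  df$subset <- canonical_subset(df$subset)
  df$mtl_kb <- mtl_from_fluorescence(df$sample_signal, df$sample_background,
                                     df$control_signal,
                                     df$control_background,
                                     df$control_length_kb)
  key <- interaction(df$subject_id, df$subset, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    m <- merge_duplicates(d$mtl_kb, tolerance_kb)
    data.frame(subject_id = d$subject_id[1], subset = d$subset[1],
               mtl_kb = m$mtl_kb, n_duplicates = nrow(d),
               flagged = m$flagged, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
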