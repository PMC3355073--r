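#' Read a cohort table from delimited text
#'
#' Accepts the canonical long format (columns \code{subject_id},
#' \code{age_years}, \code{sex}, \code{group}, \code{subset}, \code{mtl_kb})
#' or a wide layout with one row per subject and one MTL column per subset
#' (canonical subset names or immunophenotype aliases as column headers);
#' wide tables are pivoted to long on read. Rows with a non-numeric,
#' non-finite or non-positive MTL are dropped with a message, as are empty
#' wide-format cells (a subject simply lacks that subset). Ages "0" and
#' "0.0" both encode cord blood.
#'
#' @param path CSV file path.
#' @param sep field separator, default comma.
#' @return a \code{cohort_table} data frame (long format).
#' @export
read_cohort <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  long <- if (all(c("subset", "mtl_kb") %in% names(raw))) {
    raw
  } else {
    .wide_to_long(raw)
  }
  need <- c("subject_id", "age_years", "sex", "group", "subset", "mtl_kb")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "))
  long$subset <- canonical_subset(long$subset)
  bad_grp <- setdiff(unique(long$group), TELO_GROUPS)
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         "; accepted: ", paste(TELO_GROUPS, collapse = ", "))
  mtl <- suppressWarnings(as.numeric(long$mtl_kb))
  ok <- is.finite(mtl) & mtl > 0
  if (any(!ok))
    message("dropped ", sum(!ok), " row(s) with invalid MTL")
  long <- long[ok, need]
  long$mtl_kb <- mtl[ok]
  long$age_years <- as.numeric(long$age_years)
  if (any(!is.finite(long$age_years)) || any(long$age_years < 0))
    stop("ages must be finite and >= 0")
  if (anyDuplicated(long[c("subject_id", "subset")]))
    stop("duplicate (subject_id, subset) records")
  rownames(long) <- NULL
  class(long) <- c("cohort_table", "data.frame")
  long
}

# pivot a wide per-subject table (one MTL column per subset) to long format
.wide_to_long <- function(raw) {
  id_cols <- intersect(c("subject_id", "age_years", "sex", "group"),
                       names(raw))
  if (!all(c("subject_id", "age_years") %in% id_cols))
    stop("wide cohort file needs subject_id and age_years columns")
  subset_cols <- setdiff(names(raw), id_cols)
  canonical_subset(subset_cols)  # errors on unknown headers
  out <- lapply(subset_cols, function(col) {
    d <- raw[id_cols]
    if (!"sex" %in% names(d)) d$sex <- "unknown"
    if (!"group" %in% names(d)) d$group <- "healthy"
    d$subset <- col
    d$mtl_kb <- raw[[col]]
    d
  })
  long <- do.call(rbind, out)
  long[!is.na(long$mtl_kb) & long$mtl_kb != "", ]
}

#' Write a cohort table as CSV
#'
#' @param cohort a \code{cohort_table}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a piecewise fit to flat JSON
#'
#' Stores the fitted coefficients (intercept in kb, slopes in kb/yr),
#' breakpoints, RSS, n and the residuals, so bands can be rebuilt on load.
#'
#' @param fit a \code{piecewise_fit}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(intercept_kb = fit$params$intercept_kb,
         slope1_kb_per_yr = fit$params$slopes_kb_yr[1],
         slope2_kb_per_yr = fit$params$slopes_kb_yr[2],
         slope3_kb_per_yr = fit$params$slopes_kb_yr[3],
         breakpoints = fit$params$breakpoints,
         rss = fit$rss, n = fit$n, df_residual = fit$df_residual,
         mse = fit$mse, age_range = fit$age_range,
         residuals = fit$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @return \code{read_fit}: a \code{piecewise_fit} (without fitted values).
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(params = piecewise_params(
           x$intercept_kb,
           c(x$slope1_kb_per_yr, x$slope2_kb_per_yr, x$slope3_kb_per_yr),
           x$breakpoints),
         residuals = x$residuals,
         fitted = NULL,
         rss = x$rss, df_residual = x$df_residual, n = x$n, mse = x$mse,
         age_range = x$age_range),
    class = "piecewise_fit")
}

#' Serialise a band set (fit parameters plus one shift per level)
#'
#' @param band a \code{band_set}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_bands <- function(band, path) {
  jsonlite::write_json(
    list(intercept_kb = band$fit$params$intercept_kb,
         slopes_kb_per_yr = band$fit$params$slopes_kb_yr,
         breakpoints = band$fit$params$breakpoints,
         levels = band$levels,
         shifts_kb = unname(band$shifts),
         residuals = band$fit$residuals,
         n = band$fit$n, rss = band$fit$rss,
         df_residual = band$fit$df_residual, mse = band$fit$mse,
         age_range = band$fit$age_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bands
#' @return \code{read_bands}: a \code{band_set}.
#' @export
read_bands <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(
    list(params = piecewise_params(x$intercept_kb, x$slopes_kb_per_yr,
                                   x$breakpoints),
         residuals = x$residuals, fitted = NULL, rss = x$rss,
         df_residual = x$df_residual, n = x$n, mse = x$mse,
         age_range = x$age_range),
    class = "piecewise_fit")
  structure(list(fit = fit, levels = x$levels,
                 shifts = stats::setNames(x$shifts_kb, format(x$levels))),
            class = "band_set")
}

#' Run the full reference-range pipeline
#'
#' Chains the analysis stages: simulate (or load) a cohort, fit the hinged
#' piecewise model per subset on the healthy records, build percentile
#' bands, screen every record against the healthy reference, and test the
#' sex effect on each subset's trend with the nested-model F-test. All stage
#' outputs are written under \code{out_dir} as CSV/JSON; the run is fully
#' deterministic for a fixed config.
#'
#' @param config a \code{generator_config} used when \code{cohort} is NULL.
#' @param cohort optional pre-loaded \code{cohort_table}; when supplied the
#'   simulation stage is skipped.
#' @param n_per_group passed to [generate_cohort()] when simulating.
#' @param levels band levels.
#' @param out_dir optional output directory; when NULL nothing is written.
#' @return list with \code{cohort}, \code{fits}, \code{bands},
#'   \code{screen}, \code{screen_by_group}, \code{sex_tests}.
#' @export
run_pipeline <- function(config = default_healthy_config(),
                         cohort = NULL, n_per_group = NULL,
                         levels = c(0.01, 0.10, 0.50, 0.90, 0.99),
                         out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config, n_per_group)
  healthy <- cohort[cohort$group == "healthy", ]
  if (nrow(healthy) == 0L) stop("pipeline needs healthy reference records")
  subsets <- unique(cohort$subset)
  fits <- lapply(stats::setNames(subsets, subsets), function(ss) {
    h <- healthy[healthy$subset == ss, ]
    fit_piecewise(h$age_years, h$mtl_kb)
  })
  bands <- lapply(fits, reference_bands, levels = levels)
  screen <- screen_cohort(cohort, bands)
  sex_tests <- lapply(stats::setNames(subsets, subsets), function(ss) {
    h <- healthy[healthy$subset == ss, ]
    nested_f_test(h$age_years, h$mtl_kb, h$sex)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    for (ss in subsets) {
      write_fit(fits[[ss]], file.path(out_dir, paste0("fit_", ss, ".json")))
      write_bands(bands[[ss]],
                  file.path(out_dir, paste0("bands_", ss, ".json")))
    }
    utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
  }
  list(cohort = cohort, fits = fits, bands = bands, screen = screen,
       screen_by_group = screen_summary(screen), sex_tests = sex_tests)
}
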