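#' Configuration of the synthetic cross-sectional cohort generator
#'
#' Bundles everything the generator needs to emulate a flow-FISH telomere
#' length study: one piecewise age trend and residual spread per leukocyte
#' subset, an additive female-minus-male offset, additive group deficits for
#' mutation carriers and their relatives, the cohort density (subjects per
#' age-year), the age range, age laws for the non-healthy groups, an optional
#' per-subset missingness rate and the random seed.
#'
#' @param subset_params named list mapping each subset label to a
#'   \code{piecewise_params} object (kb and kb/yr).
#' @param subset_sd named numeric: residual standard deviation per subset, kb.
#' @param sex_offset named numeric: additive female-minus-male MTL shift per
#'   subset, kb. The offset is applied symmetrically (+offset/2 for females,
#'   -offset/2 for males) so the pooled-sex mean stays on the subset trend.
#' @param group_deltas named list mapping a group label to a named numeric
#'   vector of additive MTL deficits per subset, kb (negative = shorter than
#'   the healthy trend). The healthy group implicitly has delta 0.
#' @param subjects_per_age_year healthy-cohort density, subjects per age-year.
#' @param cord_blood_n number of cord-blood subjects (age 0 exactly) in the
#'   healthy cohort, oversampled relative to the per-age-year density the way
#'   reference studies oversample birth to pin down the steep infancy trend.
#'   \code{NULL} means no oversampling (\code{subjects_per_age_year} at age 0
#'   too).
#' @param age_range numeric length 2, years; minimum must be \code{>= 0}.
#' @param age_laws named list mapping non-healthy group labels to a truncated
#'   normal age law \code{list(mean=, sd=, min=, max=)}, years.
#' @param missing_rate probability in \code{[0, 1]} that a subject lacks a
#'   given subset measurement (emulates insufficient cells). Default 0.
#' @param seed integer random seed; generation is bit-reproducible for a
#'   fixed config.
#' @return an object of class \code{"generator_config"}.
#' @seealso [default_healthy_config()], [default_affected_config()],
#'   [generate_cohort()]
#' @export
generator_config <- function(subset_params, subset_sd, sex_offset,
                             group_deltas = list(),
                             subjects_per_age_year = 8,
                             cord_blood_n = NULL,
                             age_range = c(0, 102),
                             age_laws = list(),
                             missing_rate = 0,
                             seed = 1L) {
  stopifnot(is.list(subset_params), length(subset_params) >= 1,
            all(vapply(subset_params, inherits, TRUE, "piecewise_params")),
            subjects_per_age_year >= 1,
            length(age_range) == 2L, age_range[1] >= 0,
            age_range[2] > age_range[1],
            missing_rate >= 0, missing_rate <= 1)
  subsets <- names(subset_params)
  if (is.null(subsets) || any(subsets == ""))
    stop("subset_params must be a named list")
  check_names <- function(x, what) {
    extra <- setdiff(names(x), subsets)
    if (length(extra))
      stop(what, " names not present in subset_params: ",
           paste(extra, collapse = ", "))
  }
  check_names(subset_sd, "subset_sd")
  check_names(sex_offset, "sex_offset")
  if (any(subset_sd < 0)) stop("subset_sd must be non-negative")
  for (g in names(group_deltas)) check_names(group_deltas[[g]], "group_deltas")
  structure(
    list(subset_params = subset_params,
         subset_sd = subset_sd,
         sex_offset = sex_offset,
         group_deltas = group_deltas,
         subjects_per_age_year = subjects_per_age_year,
         cord_blood_n = if (is.null(cord_blood_n)) NULL
                        else as.integer(cord_blood_n),
         age_range = as.numeric(age_range),
         age_laws = age_laws,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "generator_config")
}

# Subset-wise trend table used by the default configs: birth intercept (kb),
# segment slopes (bp/yr, converted to kb/yr on construction) and the central
# 10th-90th percentile spread (kb) of the healthy distribution.
.default_trend_table <- function() {
  data.frame(
    subset = TELO_SUBSETS,
    intercept_kb = c(11.2, 10.3, 10.9, 11.1, 11.4, 12.4),
    slope1_bp = c(-1190, -485, -916, -947, -2073, -2818),
    slope2_bp = c(-126, -74, -70, -89, -144, -155),
    slope3_bp = c(-43, -28, -27, -51, -32, -39),
    spread_10_90_kb = c(2.45, 2.67, 2.37, 2.80, 2.28, 2.89))
}

# Table of age-adjusted group deficits (kb) per subset, in TELO_SUBSETS order.
.default_delta_table <- function() {
  list(
    carrier_TERT         = c(-2.6, -2.9, -2.7, -3.1, -2.3, -2.5),
    carrier_TERC         = c(-2.8, -2.9, -2.9, -3.3, -2.3, -2.1),
    relative_unspecified = c(-0.6, -0.9, -0.6, -0.7, -0.6, -0.6),
    relative_parent      = c(-0.9, -0.8, -0.8, -1.1, -0.8, -0.6),
    relative_sibling     = c(-0.7, -0.7, -0.8, -0.9, -0.8, -0.6))
}

#' Default generator configuration for a healthy reference cohort
#'
#' Parameterises the generator with the published subset-specific trends:
#' birth intercepts and the three segment slopes per subset (slopes given in
#' bp/yr and converted to kb/yr), plus Gaussian residual noise whose standard
#' deviation is chosen so the central 10th-90th interquantile width of the
#' noise equals the published per-subset spread, i.e.
#' \code{sd = spread / (qnorm(0.9) - qnorm(0.1))}. Sex offsets are small and
#' female-positive, largest for the naive T subset where the gender effect is
#' strongest; they are split +/- offset/2 around the subset mean so the
#' pooled-sex trend is unchanged. Only the healthy group is configured.
#'
#' The age-0 bin is oversampled to 58 cord-blood subjects, mirroring the
#' cord-blood series of the study design this generator emulates; pinning
#' down birth is what identifies the steep (about -1.2 kb/yr) infancy slope.
#'
#' @param subjects_per_age_year subjects per age-year; the default 8 over
#'   ages 0-102, together with the 58 cord-blood subjects, gives a cohort of
#'   ~874 subjects.
#' @param cord_blood_n cord-blood oversample at age 0, default 58.
#' @param seed integer random seed.
#' @return a \code{generator_config}.
#' @examples
#' cfg <- default_healthy_config(seed = 42)
#' cfg$subset_params$lymphocytes
#' @export
default_healthy_config <- function(subjects_per_age_year = 8,
                                   cord_blood_n = 58, seed = 1L) {
  tab <- .default_trend_table()
  params <- lapply(seq_len(nrow(tab)), function(i)
    piecewise_params(tab$intercept_kb[i],
                     c(tab$slope1_bp[i], tab$slope2_bp[i], tab$slope3_bp[i]) / 1000))
  names(params) <- tab$subset
  z_width <- stats::qnorm(0.90) - stats::qnorm(0.10)
  sds <- stats::setNames(tab$spread_10_90_kb / z_width, tab$subset)
  sex_off <- stats::setNames(c(0.3, 0.1, 0.3, 0.4, 0.3, 0.3), tab$subset)
  generator_config(subset_params = params,
                   subset_sd = sds,
                   sex_offset = sex_off,
                   group_deltas = list(),
                   subjects_per_age_year = subjects_per_age_year,
                   cord_blood_n = cord_blood_n,
                   age_range = c(0, 102),
                   seed = seed)
}

#' Default generator configuration including carriers and relatives
#'
#' Extends [default_healthy_config()] with age-adjusted MTL deficits for
#' heterozygous telomerase-mutation carriers (separate values for hTERT and
#' hTERC carriers) and for their non-carrier relatives (pooled, parents and
#' siblings), and with truncated-normal age laws: carrier ages centred at 41
#' years and relative ages at 45 years, both restricted to the adult segment
#' (19+ years) by default.
#'
#' @inheritParams default_healthy_config
#' @return a \code{generator_config} with \code{group_deltas} and
#'   \code{age_laws} populated for the carrier and relative groups.
#' @examples
#' cfg <- default_affected_config()
#' cfg$group_deltas$carrier_TERT
#' @export
default_affected_config <- function(subjects_per_age_year = 8,
                                    cord_blood_n = 58, seed = 1L) {
  cfg <- default_healthy_config(subjects_per_age_year, cord_blood_n, seed)
  deltas <- lapply(.default_delta_table(), stats::setNames, TELO_SUBSETS)
  cfg$group_deltas <- deltas
  carrier_law  <- list(mean = 41, sd = 12, min = 19, max = cfg$age_range[2])
  relative_law <- list(mean = 45, sd = 12, min = 19, max = cfg$age_range[2])
  cfg$age_laws <- list(carrier_TERT = carrier_law,
                       carrier_TERC = carrier_law,
                       relative_unspecified = relative_law,
                       relative_parent = relative_law,
                       relative_sibling = relative_law)
  cfg
}

# inverse-CDF draw from a normal truncated to [law$min, law$max]
.rtruncnorm <- function(n, law) {
  lo <- stats::pnorm(law$min, law$mean, law$sd)
  hi <- stats::pnorm(law$max, law$mean, law$sd)
  stats::qnorm(stats::runif(n, lo, hi), law$mean, law$sd)
}

#' Generate a synthetic cross-sectional telomere cohort
#'
#' Draws one record per subject and subset. Healthy subjects are spread
#' uniformly over integer age-year bins across the configured age range so
#' the cohort has about \code{subjects_per_age_year} subjects per age-year,
#' with the age-0 (cord blood, encoded as age 0 exactly) bin oversampled to
#' \code{cord_blood_n} subjects; bin k draws ages uniformly in (k-1, k].
#' When an explicit healthy count is requested instead, subjects are spread
#' evenly over all bins. Carrier and relative ages come from the
#' group's truncated-normal age law. Each measurement is
#' \deqn{MTL = trend(age) \pm sexoffset/2 + groupdelta + N(0, sd)}
#' with subset-specific trend, offset, delta and Gaussian noise. Subset
#' noises are drawn independently within a subject.
#'
#' @param config a \code{generator_config}.
#' @param n_per_group named integer vector of subject counts per group label.
#'   For \code{healthy} the count defaults to
#'   \code{subjects_per_age_year * number_of_age_year_bins} when omitted.
#' @return A long-format data frame of class \code{"cohort_table"} with
#'   columns \code{subject_id}, \code{age_years}, \code{sex}, \code{group},
#'   \code{subset}, \code{mtl_kb}; \code{(subject_id, subset)} pairs are
#'   unique.
#' @examples
#' cohort <- generate_cohort(default_healthy_config(seed = 7))
#' nrow(cohort) / length(TELO_SUBSETS)  # ~874 subjects
#' @export
generate_cohort <- function(config, n_per_group = NULL) {
  stopifnot(inherits(config, "generator_config"))
  lo <- ceiling(config$age_range[1]); hi <- floor(config$age_range[2])
  cord_n <- config$cord_blood_n
  if (is.null(cord_n) || lo > 0) cord_n <- config$subjects_per_age_year
  default_healthy_n <- if (lo == 0)
    cord_n + config$subjects_per_age_year * (hi - 1L + 1L)
  else
    config$subjects_per_age_year * (hi - lo + 1L)
  if (is.null(n_per_group))
    n_per_group <- c(healthy = default_healthy_n)
  bad_groups <- setdiff(names(n_per_group), TELO_GROUPS)
  if (length(bad_groups))
    stop("unknown group label(s) in n_per_group: ",
         paste(bad_groups, collapse = ", "),
         "; accepted: ", paste(TELO_GROUPS, collapse = ", "))
  if (any(n_per_group < 0)) stop("group counts must be >= 0")

  set.seed(config$seed)
  subsets <- names(config$subset_params)
  rows <- list()
  sid <- 0L

  for (grp in names(n_per_group)) {
    n <- as.integer(n_per_group[[grp]])
    if (n == 0L) next
    if (grp == "healthy") {
      bin <- if (lo == 0 && n == default_healthy_n)
        c(rep(0L, cord_n),
          rep(seq(1L, hi), each = config$subjects_per_age_year))
      else
        rep(seq(lo, hi), length.out = n)  # explicit count: even spread
      u <- stats::runif(n)
      age <- ifelse(bin == 0, 0, bin - 1 + u)  # bin 0 = cord blood, exact
    } else {
      law <- config$age_laws[[grp]]
      if (is.null(law))
        stop("no age law configured for group '", grp, "'")
      age <- .rtruncnorm(n, law)
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    delta <- config$group_deltas[[grp]]
    ids <- sprintf("%s_%04d", grp, sid + seq_len(n))
    sid <- sid + n
    for (ss in subsets) {
      mu <- predict(config$subset_params[[ss]], age)
      off <- config$sex_offset[[ss]]
      if (is.null(off) || is.na(off)) off <- 0
      d <- if (!is.null(delta) && ss %in% names(delta)) delta[[ss]] else 0
      sd_ss <- config$subset_sd[[ss]]
      if (is.null(sd_ss) || is.na(sd_ss)) sd_ss <- 0
      mtl <- mu + ifelse(sex == "F", off / 2, -off / 2) + d +
        stats::rnorm(n, 0, sd_ss)
      keep <- if (config$missing_rate > 0)
        stats::runif(n) >= config$missing_rate else rep(TRUE, n)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[keep], age_years = age[keep], sex = sex[keep],
        group = grp, subset = ss, mtl_kb = mtl[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
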