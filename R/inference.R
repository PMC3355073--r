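#' Nested-model F-test for a factor effect on the age trend
#'
#' Compares a single pooled piecewise fit against fully stratified fits (one
#' complete 4-coefficient piecewise curve per factor level) with an ANOVA
#' F-test:
#' \deqn{F = \frac{(RSS_1 - RSS_2)/(df_1 - df_2)}{RSS_2/df_2}}
#' where model 1 is pooled and model 2 stratified. For a two-level factor on
#' the three-segment model the numerator has 4 degrees of freedom (one extra
#' curve's intercept and three slopes) and the denominator n - 8. This is
#' the test of, e.g., whether females and males follow different telomere
#' trajectories.
#'
#' @param age,mtl_kb data vectors.
#' @param factor_labels vector with one level label per observation,
#'   \code{>= 2} levels.
#' @param breakpoints hinge locations shared by all fits.
#' @return list of class \code{"nested_f_test"}: \code{rss_pooled},
#'   \code{rss_stratified}, \code{df_pooled}, \code{df_stratified},
#'   \code{f_stat}, \code{df_num}, \code{df_den}, \code{p_value},
#'   \code{levels}.
#' @examples
#' cohort <- generate_cohort(default_healthy_config(seed = 5))
#' nt <- cohort[cohort$subset == "naiveT_CD45RAposCD20neg", ]
#' nested_f_test(nt$age_years, nt$mtl_kb, nt$sex)
#' @export
nested_f_test <- function(age, mtl_kb, factor_labels, breakpoints = c(1, 18)) {
  f <- as.factor(factor_labels)
  lev <- levels(droplevels(f))
  if (length(lev) < 2L)
    stop("factor must have at least 2 levels; got: ",
         paste(lev, collapse = ", "))
  pooled <- fit_piecewise(age, mtl_kb, breakpoints)
  strat <- lapply(lev, function(l) {
    idx <- f == l
    tryCatch(fit_piecewise(age[idx], mtl_kb[idx], breakpoints),
             error = function(e)
               stop("stratum '", l, "' cannot be fitted: ",
                    conditionMessage(e), call. = FALSE))
  })
  rss1 <- pooled$rss
  rss2 <- sum(vapply(strat, `[[`, numeric(1), "rss"))
  df1 <- pooled$df_residual
  df2 <- sum(vapply(strat, `[[`, integer(1), "df_residual"))
  df_num <- df1 - df2
  f_stat <- ((rss1 - rss2) / df_num) / (rss2 / df2)
  structure(
    list(rss_pooled = rss1, rss_stratified = rss2,
         df_pooled = df1, df_stratified = df2,
         f_stat = f_stat, df_num = df_num, df_den = df2,
         p_value = stats::pf(f_stat, df_num, df2, lower.tail = FALSE),
         levels = lev),
    class = "nested_f_test")
}

#' @export
print.nested_f_test <- function(x, ...) {
  cat(sprintf("Nested piecewise-model ANOVA (%s)\n",
              paste(x$levels, collapse = " vs ")))
  cat(sprintf("  RSS pooled %.3f (df %d) | stratified %.3f (df %d)\n",
              x$rss_pooled, x$df_pooled, x$rss_stratified, x$df_stratified))
  cat(sprintf("  F(%d,%d) = %.3f, p = %.3g\n",
              x$df_num, x$df_den, x$f_stat, x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition, computed with [stats::lm()] /
#' [stats::anova()]. Used e.g. to compare cord-blood telomere length across
#' the six leukocyte subsets.
#'
#' @param groups list of numeric samples (one per group), or a single
#'   numeric vector together with \code{labels}.
#' @param labels optional group labels when \code{groups} is a vector.
#' @return list with \code{f_stat}, \code{df_between}, \code{df_within},
#'   \code{p_value}.
#' @export
one_way_anova <- function(groups, labels = NULL) {
  if (is.list(groups)) {
    values <- unlist(groups, use.names = FALSE)
    labels <- rep(seq_along(groups), lengths(groups))
  } else {
    values <- groups
    if (is.null(labels) || length(labels) != length(values))
      stop("labels required (one per observation) when groups is a vector")
  }
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 1L)) stop("every group needs at least 1 observation")
  if (length(values) <= nlevels(g))
    stop("total n must exceed the number of groups")
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  # all group means identical (e.g. constant data): F = 0 by convention,
  # avoiding the 0/0 the decomposition would produce
  if (isTRUE(all.equal(stats::var(tapply(values, g, mean)), 0,
                       tolerance = 1e-24)))
    return(list(f_stat = 0, df_between = df_b, df_within = df_w,
                p_value = 1))
  a <- stats::anova(stats::lm(values ~ g))
  list(f_stat = a$`F value`[1],
       df_between = a$Df[1],
       df_within = a$Df[2],
       p_value = a$`Pr(>F)`[1])
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All pairwise group comparisons at the one-way-ANOVA pooled within-group
#' mean square, with studentized-range adjusted p-values from
#' [stats::ptukey()]. For unequal group sizes the Tukey-Kramer standard
#' error is used.
#'
#' @inheritParams one_way_anova
#' @return data frame with one row per pair: \code{pair}, \code{mean_diff},
#'   \code{se}, \code{q_stat}, \code{p_adj}.
#' @export
tukey_hsd <- function(groups, labels = NULL) {
  if (!is.list(groups)) {
    if (is.null(labels)) stop("labels required when groups is a vector")
    groups <- split(groups, factor(labels))
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df_w <- sum(ns) - k
  if (df_w < 1L) stop("no within-group degrees of freedom")
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df_w
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))  # Tukey-Kramer
    q <- abs(diff) / se
    p <- if (mse == 0) as.numeric(diff == 0) else
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    data.frame(pair = paste(names(groups)[j], "-", names(groups)[i]),
               mean_diff = diff, se = se, q_stat = q, p_adj = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed Student's t-test with pooled variance. Degenerate inputs where
#' both samples are constant return t = 0, p = 1 when the means are equal
#' (no evidence of any difference) and t = +/-Inf, p = 0 otherwise.
#'
#' @param a,b numeric samples, each of size \code{>= 2}.
#' @return list with \code{t_stat}, \code{df}, \code{p_two_tailed},
#'   \code{mean_diff}.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 observations")
  df <- na + nb - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  md <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  list(t_stat = t, df = df, p_two_tailed = p, mean_diff = md)
}
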