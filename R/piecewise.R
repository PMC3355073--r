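#' Piecewise-linear telomere trend parameters
#'
#' Constructs the parameter set of a continuous three-segment piecewise-linear
#' ("hinged") model of median telomere length (MTL, kb) versus age (years).
#' The curve starts at \code{intercept_kb} at birth and changes slope at the
#' two breakpoints while remaining continuous; by convention the breakpoints
#' sit at 1 year (end of infancy) and 18 years (end of childhood), where
#' leukocyte telomere attrition decelerates markedly.
#'
#' @param intercept_kb MTL at age 0 (birth / cord blood), in kb.
#' @param slopes_kb_yr numeric vector of length 3: attrition rates in kb/year
#'   for the segments \code{[0, b1]}, \code{(b1, b2]} and \code{(b2, Inf)}.
#'   Negative values encode telomere loss.
#' @param breakpoints strictly increasing positive numeric vector of length 2,
#'   in years. Default \code{c(1, 18)}.
#' @return An object of class \code{"piecewise_params"}: a list with elements
#'   \code{intercept_kb}, \code{slopes_kb_yr} and \code{breakpoints}.
#' @examples
#' p <- piecewise_params(11.2, c(-1.190, -0.126, -0.043))
#' predict(p, age = c(0, 1, 18, 102))
#' @seealso [fit_piecewise()], [predict.piecewise_params()]
#' @export
piecewise_params <- function(intercept_kb, slopes_kb_yr, breakpoints = c(1, 18)) {
  stopifnot(is.numeric(intercept_kb), length(intercept_kb) == 1L,
            is.numeric(slopes_kb_yr), length(slopes_kb_yr) == 3L,
            is.numeric(breakpoints), length(breakpoints) == 2L)
  if (!(breakpoints[1] > 0 && breakpoints[2] > breakpoints[1]))
    stop("breakpoints must satisfy 0 < b1 < b2")
  structure(
    list(intercept_kb = as.numeric(intercept_kb),
         slopes_kb_yr = as.numeric(slopes_kb_yr),
         breakpoints  = as.numeric(breakpoints)),
    class = "piecewise_params")
}

#' @export
print.piecewise_params <- function(x, ...) {
  b <- x$breakpoints
  cat("Hinged piecewise-linear telomere trend\n")
  cat(sprintf("  intercept (birth): %.3f kb\n", x$intercept_kb))
  cat(sprintf("  slopes: [0,%g] %.4f | (%g,%g] %.4f | >%g %.4f kb/yr\n",
              b[1], x$slopes_kb_yr[1], b[1], b[2], x$slopes_kb_yr[2],
              b[2], x$slopes_kb_yr[3]))
  invisible(x)
}

#' Hinge basis for the three-segment age model
#'
#' Expands ages into the four-column design basis
#' \code{[1, min(age, b1), clamp(age - b1, 0, b2 - b1), max(age - b2, 0)]}
#' whose coefficients are the birth intercept and the three segment slopes.
#' Because each hinge column is continuous in age, any linear combination of
#' the basis is continuous at both breakpoints, so continuity of the fitted
#' curve is enforced structurally rather than as a constraint.
#'
#' @param age numeric vector of ages in years, all \code{>= 0}.
#' @param breakpoints breakpoints in years, strictly increasing, length 2.
#' @return A numeric matrix with \code{length(age)} rows and 4 columns
#'   named \code{intercept}, \code{seg1}, \code{seg2}, \code{seg3}.
#' @examples
#' hinge_design(c(0.5, 18, 25), c(1, 18))
#' @export
hinge_design <- function(age, breakpoints = c(1, 18)) {
  stopifnot(is.numeric(age), all(is.finite(age)), all(age >= 0),
            length(breakpoints) == 2L, breakpoints[1] > 0,
            breakpoints[2] > breakpoints[1])
  b1 <- breakpoints[1]; b2 <- breakpoints[2]
  X <- cbind(intercept = rep(1, length(age)),
             seg1 = pmin(age, b1),
             seg2 = pmin(pmax(age - b1, 0), b2 - b1),
             seg3 = pmax(age - b2, 0))
  X
}

#' Predict MTL at given ages from piecewise parameters
#'
#' Evaluates the continuous piecewise-linear curve. The values at ages 0, 1,
#' 18 and the oldest reference age are the conventional summary of a fitted
#' trend (birth, end-of-infancy, adult-onset and old-age regression MTLs).
#'
#' @param object a \code{piecewise_params} object.
#' @param age numeric vector of ages in years (\code{>= 0}).
#' @param ... unused.
#' @return numeric vector of predicted MTL in kb.
#' @examples
#' p <- piecewise_params(11.2, c(-1.190, -0.126, -0.043))
#' round(predict(p, c(1, 18, 102)), 1)
#' @export
predict.piecewise_params <- function(object, age, ...) {
  X <- hinge_design(age, object$breakpoints)
  drop(X %*% c(object$intercept_kb, object$slopes_kb_yr))
}

#' Fit the hinged piecewise-linear age model by least squares
#'
#' Ordinary least squares on the hinge basis of [hinge_design()], solved by
#' QR decomposition (via [stats::lm.fit()]). Breakpoints are fixed a priori,
#' not estimated. The model has 4 coefficients (intercept + three slopes), so
#' the residual degrees of freedom are \code{n - 4}.
#'
#' @param age numeric vector of ages in years.
#' @param mtl_kb numeric vector of median telomere lengths in kb, same length.
#' @param breakpoints fixed hinge locations in years. Default \code{c(1, 18)}.
#' @return An object of class \code{"piecewise_fit"}: a list with
#'   \describe{
#'     \item{params}{fitted \code{piecewise_params}}
#'     \item{residuals}{observed minus predicted, kb}
#'     \item{fitted}{predicted values, kb}
#'     \item{rss}{residual sum of squares, kb^2}
#'     \item{df_residual}{\code{n - 4}}
#'     \item{n}{number of observations}
#'     \item{mse}{mean squared error \code{rss / n}, kb^2}
#'   }
#' @details The design is rank-deficient when the data do not span a segment
#'   (for instance all ages below 1 year leave the childhood and adult slopes
#'   free); this raises an error naming the unidentifiable segment rather
#'   than silently dropping coefficients.
#' @examples
#' p <- piecewise_params(11.2, c(-1.190, -0.126, -0.043))
#' age <- c(0, 0.5, 1, 5, 12, 18, 40, 60, 102)
#' fit <- fit_piecewise(age, predict(p, age))
#' fit$params
#' @export
fit_piecewise <- function(age, mtl_kb, breakpoints = c(1, 18)) {
  stopifnot(is.numeric(mtl_kb), length(age) == length(mtl_kb),
            all(is.finite(mtl_kb)))
  n <- length(age)
  if (n < 5L) stop("need at least 5 observations to fit 4 coefficients")
  X <- hinge_design(age, breakpoints)
  # a hinge column that never varies means that segment's slope cannot be
  # estimated from these ages
  seg_var <- apply(X[, -1, drop = FALSE], 2, function(col) diff(range(col)))
  if (any(seg_var == 0)) {
    bad <- names(seg_var)[seg_var == 0]
    stop("unidentifiable segment slope(s): ", paste(bad, collapse = ", "),
         " (ages do not span these segments)")
  }
  ft <- stats::lm.fit(X, mtl_kb)
  if (ft$rank < 4L)
    stop("rank-deficient hinge design: ages do not identify all 4 coefficients")
  coefs <- ft$coefficients
  # recompute fitted values as X %*% beta so that stored residuals agree
  # bitwise with mtl_kb - predict(params, age): in-sample band coverage is
  # then an exact counting identity, not a floating-point coin flip
  beta <- c(coefs[["intercept"]], unname(coefs[c("seg1", "seg2", "seg3")]))
  fitted <- drop(X %*% beta)
  res <- mtl_kb - fitted
  rss <- sum(res^2)
  structure(
    list(params = piecewise_params(beta[1], beta[2:4], breakpoints),
         residuals = res,
         fitted = fitted,
         rss = rss,
         df_residual = n - 4L,
         n = n,
         mse = rss / n,
         age_range = range(age)),
    class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise fit: n = %d, RSS = %.4f kb^2, residual df = %d\n",
              x$n, x$rss, x$df_residual))
  print(x$params)
  invisible(x)
}

#' @rdname predict.piecewise_params
#' @export
predict.piecewise_fit <- function(object, age, ...) {
  predict(object$params, age, ...)
}

#' Compare the piecewise age model with a polynomial fit
#'
#' Fits the hinged piecewise model and an ordinary polynomial of the given
#' degree to the same data, and reports each model's mean squared error
#' together with the mean residual within each age segment (a simple
#' diagnostic of how evenly the error is distributed across infancy,
#' childhood and adulthood). The winner is the model with the lower MSE.
#'
#' @param age,mtl_kb data vectors as in [fit_piecewise()].
#' @param degree polynomial degree, one of 1:4.
#' @param breakpoints hinge locations for the piecewise model (also used to
#'   bin the per-segment residual diagnostic).
#' @return A list with \code{mse_piecewise}, \code{mse_polynomial},
#'   \code{winner} (\code{"piecewise"}, \code{"polynomial"} or \code{"tie"}),
#'   and \code{segment_mean_residuals}, a data frame with one row per age
#'   segment and the mean residual of each model within it.
#' @export
compare_to_polynomial <- function(age, mtl_kb, degree = 2,
                                  breakpoints = c(1, 18)) {
  stopifnot(degree %in% 1:4)
  n <- length(age)
  if (n <= degree + 1 || n <= 4)
    stop("too few observations for the requested comparison")
  pw <- fit_piecewise(age, mtl_kb, breakpoints)
  poly_fit <- stats::lm(mtl_kb ~ stats::poly(age, degree, raw = TRUE))
  res_poly <- as.numeric(stats::residuals(poly_fit))
  mse_poly <- sum(res_poly^2) / n

  seg <- cut(age, c(-Inf, breakpoints, Inf),
             labels = c("infancy", "childhood", "adult"))
  seg_tab <- data.frame(
    segment = levels(seg),
    mean_residual_piecewise = as.numeric(tapply(pw$residuals, seg, mean)),
    mean_residual_polynomial = as.numeric(tapply(res_poly, seg, mean)))

  winner <- if (isTRUE(all.equal(pw$mse, mse_poly))) "tie"
            else if (pw$mse < mse_poly) "piecewise" else "polynomial"
  list(mse_piecewise = pw$mse,
       mse_polynomial = mse_poly,
       winner = winner,
       degree = degree,
       segment_mean_residuals = seg_tab)
}
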