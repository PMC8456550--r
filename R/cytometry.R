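#' Median size-normalized fluorescence of one well
#'
#' Cell size and fluorescence are strongly correlated, so raw median
#' fluorescence confounds expression with the size distribution of the
#' sample. Within each well, log-fluorescence is regressed on log-size and
#' the normalized per-cell value is \code{exp(residual + mean log
#' fluorescence)}; the well summary is the median of these values. If
#' fluorescence is exactly proportional to size the result is independent of
#' the size distribution, and doubling every fluorescence doubles the output.
#'
#' @param size,fluorescence positive per-cell measurements (same length, at
#'   least 100 events).
#' @return the median normalized fluorescence (scalar).
#' @export
summarize_well <- function(size, fluorescence) {
  stopifnot(length(size) == length(fluorescence))
  if (length(size) < 100) stop("need at least 100 events per well")
  if (any(size <= 0) || any(fluorescence <= 0)) {
    stop("size and fluorescence must be positive")
  }
  ls <- log(size); lf <- log(fluorescence)
  if (stats::sd(ls) < .Machine$double.eps^0.5) {
    warning("degenerate cell-size variance; returning raw median fluorescence")
    return(stats::median(fluorescence))
  }
  fit <- stats::lm.fit(cbind(1, ls), lf)
  stats::median(exp(fit$residuals + mean(lf)))
}

#' Correct plate position effects estimated from control wells
#'
#' Fits \code{value ~ row + col} (numeric coordinates, 3 parameters) on the
#' control wells of each plate and subtracts each well's fitted positional
#' deviation from the control mean. By construction the mean of the control
#' wells on a plate is unchanged. Plates with fewer than 3 control wells are
#' left uncorrected with a warning.
#'
#' @param wells data frame with columns \code{plate_id}, \code{row},
#'   \code{col}, \code{value} and logical \code{is_control}.
#' @return \code{wells} with an added column \code{corrected}.
#' @export
correct_position_effects <- function(wells) {
  need <- c("plate_id", "row", "col", "value", "is_control")
  stopifnot(all(need %in% names(wells)))
  wells$corrected <- wells$value
  for (p in unique(wells$plate_id)) {
    on_plate <- wells$plate_id == p
    ctrl <- on_plate & wells$is_control
    if (sum(ctrl) < 3) {
      warning("plate ", p, ": fewer than 3 control wells, no correction")
      next
    }
    fit <- stats::lm(value ~ row + col, data = wells[ctrl, ])
    fitted_all <- stats::predict(fit, newdata = wells[on_plate, ])
    wells$corrected[on_plate] <-
      wells$value[on_plate] - (fitted_all - mean(stats::fitted(fit)))
  }
  wells
}

#' Map fluorescence onto an expression-linear scale
#'
#' Monotone piecewise-linear interpolation in log-log space through
#' calibration anchor pairs (fluorescence, expression), extrapolating with
#' the end segments. A two-anchor curve with log-log slope k maps a 1%
#' fluorescence change to a ~k% expression change, matching the empirical
#' log-linear relation between reporter fluorescence and mRNA abundance.
#' With \code{curve = NULL} the values pass through unchanged.
#'
#' @param values positive fluorescence values.
#' @param curve data frame with columns \code{fluorescence} and
#'   \code{expression}, both strictly increasing, or \code{NULL}.
#' @return values on the expression scale.
#' @export
transform_to_expression <- function(values, curve = NULL) {
  if (is.null(curve)) return(values)
  stopifnot(all(c("fluorescence", "expression") %in% names(curve)))
  o <- order(curve$fluorescence)
  f <- curve$fluorescence[o]; e <- curve$expression[o]
  if (any(diff(f) <= 0) || any(diff(e) <= 0)) {
    stop("calibration curve must be strictly increasing in both coordinates")
  }
  if (length(f) == 1) stop("calibration curve needs at least two anchors")
  lx <- log(values)
  out <- stats::approx(log(f), log(e), xout = lx, rule = 2)$y
  # linear extrapolation beyond the anchors using the end segments
  k <- length(f)
  slope_lo <- (log(e[2]) - log(e[1])) / (log(f[2]) - log(f[1]))
  slope_hi <- (log(e[k]) - log(e[k - 1])) / (log(f[k]) - log(f[k - 1]))
  lo <- lx < log(f[1]); hi <- lx > log(f[k])
  out[lo] <- log(e[1]) + slope_lo * (lx[lo] - log(f[1]))
  out[hi] <- log(e[k]) + slope_hi * (lx[hi] - log(f[k]))
  exp(out)
}

#' Express values relative to a reference strain after autofluorescence removal
#'
#' \code{(value - autofluorescence_mean) / (reference_mean -
#' autofluorescence_mean)}: the autofluorescence baseline maps to 0 and the
#' reference mean to 1, so reference replicates average to 1 by construction.
#'
#' @param values expression values.
#' @param autofluorescence_mean mean expression of the non-fluorescent strain.
#' @param reference_mean mean expression of the reference strain (must exceed
#'   the autofluorescence mean).
#' @return relative expression values.
#' @export
normalize_to_reference <- function(values, autofluorescence_mean,
                                   reference_mean) {
  denom <- reference_mean - autofluorescence_mean
  if (!is.finite(denom) || denom <= 0) {
    stop("reference mean must exceed the autofluorescence mean")
  }
  (values - autofluorescence_mean) / denom
}

#' Drop replicate outliers by the k-MAD rule
#'
#' Removes replicate values farther than \code{k} times the median absolute
#' deviation from the replicate median. When the MAD is exactly zero nothing
#' is dropped (declared convention: a degenerate spread estimate should not
#' discard data).
#'
#' @param values numeric vector of replicate measurements (at least 3).
#' @param k multiplier on the MAD; default 5.
#' @return the retained values.
#' @export
mad_filter <- function(values, k = 5) {
  if (length(values) < 3) stop("need at least 3 replicates")
  med <- stats::median(values)
  m <- stats::median(abs(values - med))  # raw MAD, no consistency constant
  if (m == 0) return(values)
  values[abs(values - med) <= k * m]
}

#' Two-level permutation test against a replicated reference panel
#'
#' Tests whether a strain measured in 4 replicates differs in mean expression
#' from a reference strain grown at many plate positions with 4 replicates
#' each. Naive tests pooling all reference replicates are overpowered when
#' between-position variance exceeds within-position variance; this test
#' resamples at both levels. Per iteration: draw one panel position uniformly
#' at random; compute \code{D_obs}, the absolute difference between the test
#' mean and that position's mean; pool the 8 values and split them uniformly
#' at random into two sets of 4, giving a randomized difference
#' \code{D_perm}; record \code{D = D_obs - D_perm}. The p-value is the
#' fraction of negative \code{D} among the non-zero \code{D}; if every
#' \code{D} is zero the p-value is 1.
#'
#' @param test_values exactly 4 replicate values of the tested strain.
#' @param panel matrix of reference values, one row per plate position, 4
#'   columns of replicates.
#' @param n_iter number of iterations; default 10000.
#' @param seed optional integer seed.
#' @return the permutation p-value.
#' @export
two_level_permutation_test <- function(test_values, panel, n_iter = 10000,
                                       seed = NULL) {
  if (length(test_values) != 4) stop("test_values must hold exactly 4 replicates")
  panel <- as.matrix(panel)
  if (nrow(panel) < 1) stop("reference panel is empty")
  if (ncol(panel) != 4) stop("panel must have 4 replicate columns")
  if (!is.null(seed)) set.seed(seed)

  pos <- sample.int(nrow(panel), n_iter, replace = TRUE)
  pos_mean <- rowMeans(panel)[pos]
  d_obs <- abs(mean(test_values) - pos_mean)

  pooled <- cbind(matrix(test_values, n_iter, 4, byrow = TRUE),
                  panel[pos, , drop = FALSE])
  # uniform split into two sets of 4: rank a uniform draw within each row
  u <- matrix(stats::runif(n_iter * 8L), n_iter, 8L)
  o <- order(row(u), u)                       # row-major sort of u
  cols <- ((o - 1L) %/% n_iter) + 1L          # column of each sorted element
  sel <- matrix(cols, n_iter, 8L, byrow = TRUE)[, 1:4, drop = FALSE]
  g1 <- (pooled[cbind(seq_len(n_iter), sel[, 1])] +
         pooled[cbind(seq_len(n_iter), sel[, 2])] +
         pooled[cbind(seq_len(n_iter), sel[, 3])] +
         pooled[cbind(seq_len(n_iter), sel[, 4])]) / 4
  g2 <- (rowSums(pooled) - 4 * g1) / 4
  d <- d_obs - abs(g1 - g2)
  # exact ties (e.g. the random split reproducing the original grouping)
  # must count as zero despite floating-point summation-order jitter
  tol <- sqrt(.Machine$double.eps) * max(1, max(abs(pooled)))
  nz <- abs(d) > tol
  if (!any(nz)) return(1)
  sum(d < -tol) / sum(nz)
}

#' Call a significant expression change of practical size
#'
#' A strain is called changed iff its relative expression deviates from the
#' reference (1.0) by more than \code{min_effect} AND the two-level
#' permutation p-value is below \code{alpha}.
#'
#' @param relative_expression the strain's relative expression (reference = 1).
#' @param p p-value from [two_level_permutation_test()].
#' @param min_effect minimum absolute deviation from 1; default 0.01.
#' @param alpha significance level; default 0.05.
#' @return logical.
#' @export
call_expression_change <- function(relative_expression, p,
                                   min_effect = 0.01, alpha = 0.05) {
  abs(relative_expression - 1) > min_effect & p < alpha
}
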