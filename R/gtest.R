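#' Likelihood-ratio (G) test of independence for a 2x2 table
#'
#' Computes the G statistic \eqn{G = 2 \sum O \ln(O/E)} over the four cells of
#' the table \code{rbind(c(a, b), c(c, d))}, with expected counts from the
#' table margins. Cells with an observed count of zero contribute nothing to
#' the sum. The p-value is the upper tail of the chi-square distribution with
#' one degree of freedom, without continuity correction. At the conventional
#' genome-wide threshold used for bulk-segregant association, \eqn{G >
#' 10.828} corresponds to \eqn{p < 0.001}.
#'
#' @param a,b,c,d non-negative integer counts. For bulk allele counts the
#'   convention is \code{a} = reference reads in the first bulk, \code{b} =
#'   alternate reads in the first bulk, and likewise \code{c}, \code{d} for
#'   the second bulk.
#' @return a list of class \code{"g_test"} with elements \code{G}, \code{df}
#'   and \code{p}.
#' @examples
#' g_test_2x2(50, 50, 50, 50)  # identical frequencies: G = 0, p = 1
#' g_test_2x2(30, 70, 70, 30)  # G approximately 32.9
#' @export
g_test_2x2 <- function(a, b, c, d) {
  g_test_rxc(matrix(c(a, c, b, d), nrow = 2))
}

#' Likelihood-ratio (G) test of independence for an r x c table
#'
#' General form of [g_test_2x2()]: \eqn{G = 2 \sum O \ln(O/E)} with expected
#' counts from the margins and \eqn{(r-1)(c-1)} degrees of freedom. Used for
#' contrasts such as the distribution of mutations among chromosomes or among
#' coding-effect classes between mutation sets.
#'
#' @param x a matrix of non-negative counts, or anything coercible to one
#'   (e.g. the output of [table()]).
#' @return a list of class \code{"g_test"} with elements \code{G}, \code{df}
#'   and \code{p}.
#' @export
g_test_rxc <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("counts must be finite and non-negative")
  }
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    stop("undefined test: a table margin is zero")
  }
  E <- outer(rs, cs) / sum(x)
  terms <- ifelse(x == 0, 0, x * log(x / E))
  G <- 2 * sum(terms)
  G <- max(G, 0)  # guard tiny negative rounding on near-independent tables
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  structure(
    list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE)),
    class = "g_test"
  )
}

# vectorized 2x2 G statistic on parallel count vectors; 0*ln(0/E) = 0.
# used by the simulation-heavy code paths where per-call list overhead counts.
g2_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  term <- function(o, e) ifelse(o == 0, 0, o * log(o * n / e))
  G <- 2 * (term(a, r1 * c1) + term(b, r1 * c2) +
            term(c, r2 * c1) + term(d, r2 * c2))
  pmax(G, 0)
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test: G = %.4f, df = %d, p = %.4g", x$G, x$df, x$p))
  if (!is.null(x$sign)) cat(sprintf(", sign = %+d", x$sign))
  cat("\n")
  invisible(x)
}
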