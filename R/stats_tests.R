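#' Mann-Whitney U test with rank effect size
#'
#' Rank-sum comparison of two independent groups. `U` is computed by rank
#' summation with midrank ties. The two-sided p-value is exact (no ties and
#' `n1 * n2 <= 200`, via the null U distribution) or uses the normal
#' approximation with tie correction and continuity correction. The
#' reported standardized statistic `z = (U - n1 n2 / 2) / sigma_U`
#' (tie-corrected sigma, no continuity correction) feeds the effect size
#' `r = |z| / sqrt(n1 + n2)`; the rank-biserial correlation
#' `1 - 2U / (n1 n2)` is also returned.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   default chooses automatically.
#' @param correct apply the continuity correction in the normal
#'   approximation of the p-value.
#' @return An object of class `group_comparison`: list with `n1`, `n2`,
#'   `U`, `z`, `p_value`, `r`, `rank_biserial`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("validation error: both groups must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("validation error: NA values in input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- !has_ties && n1 * n2 <= 200
  mu <- n1 * n2 / 2
  tie_term <- if (has_ties) sum(ties^3 - ties) / (N * (N - 1)) else 0
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- if (sigma > 0) (U - mu) / sigma else 0
  if (exact && !has_ties) {
    p <- if (U > mu) 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
         else 2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
    method <- "exact"
  } else {
    if (sigma > 0) {
      cc <- if (correct) sign(U - mu) * 0.5 else 0
      zp <- (U - mu - cc) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(zp)))
    } else {
      p <- 1
    }
    method <- "normal approximation"
  }
  structure(list(n1 = n1, n2 = n2, U = U, z = z, p_value = p,
                 r = abs(z) / sqrt(N),
                 rank_biserial = 1 - 2 * U / (n1 * n2),
                 method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test (%s)\n  n1 = %d, n2 = %d, U = %.1f, z = %.3f\n  two-sided p = %.3g, effect size r = %.3f (rank-biserial %.3f)\n",
    x$method, x$n1, x$n2, x$U, x$z, x$p_value, x$r, x$rank_biserial))
  invisible(x)
}

#' Fisher's exact test for a 2x2 enrichment table
#'
#' Conditional hypergeometric exact test. The two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. The sample odds
#' ratio `(a d) / (b c)` is returned (`Inf` allowed when `b c = 0`).
#'
#' @param table 2x2 matrix of non-negative integer counts; rows are the
#'   groups (e.g. in-contact vs standalone), columns the outcome (e.g.
#'   cluster 1 vs cluster 2).
#' @return list with `odds_ratio`, `p_value`, `table`.
#' @export
fisher_enrichment <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("validation error: need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("validation error: counts must be non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0) return(list(odds_ratio = NaN, p_value = 1, table = table))
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p, table = table)
}
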