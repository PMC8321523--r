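#' Exact and approximate Spearman rank correlation test
#'
#' Computes Spearman's rank correlation rho together with a two-sided
#' p-value. For small samples (`n <= exact_max`, default 8) without ties the
#' p-value is exact: all `n!` rank permutations are enumerated and the
#' p-value is the proportion of permutations whose |rho| is at least the
#' observed |rho|. For larger samples, or in the presence of ties (average
#' ranks), a t-distribution approximation is used.
#'
#' The exact route matches the convention behind small-n printed values such
#' as p = 2/24 = 0.083 for four perfectly concordant (or discordant) pairs.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_max Largest n for which full permutation enumeration is
#'   attempted (default 8; 8! = 40320 permutations).
#' @return An object of class `"spearman_test"`: a list with elements
#'   `rho`, `p`, `method` (`"exact"` or `"approximate"`) and `n`.
#' @examples
#' spearman_exact(1:4, c(2, 5, 9, 11))   # rho = 1, exact p = 2/24
#' @export
spearman_exact <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")

  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L

  if (!ties && n <= exact_max) {
    perms <- .all_permutations(n)
    # rho for integer ranks 1..n: 1 - 6*sum(d^2)/(n*(n^2-1))
    denom <- n * (n^2 - 1)
    d2 <- (perms - matrix(rx, nrow(perms), n, byrow = TRUE))^2
    rho_perm <- 1 - 6 * rowSums(d2) / denom
    # permuting y against fixed x ranks is exhaustive and symmetric in x/y
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 2 * stats::pt(-Inf, df = n - 2)  # 0; degenerate under approximation
      p <- max(p, .Machine$double.xmin)
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "approximate"
  }
  structure(list(rho = rho, p = p, method = method, n = n),
            class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  rho = %.4f, two-sided p = %.4g\n", x$rho, x$p))
  invisible(x)
}

# All permutations of 1..n as a (n! x n) integer matrix, lexicographic.
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Welch / one-sample t-test
#'
#' Two-sample mode applies Welch's unequal-variance t-statistic with the
#' Welch-Satterthwaite degrees of freedom; one-sample mode tests the mean of
#' `x` against `mu0`. Always two-sided.
#'
#' A one-sample input with zero variance is degenerate: the decision is made
#' by exact comparison of the common value with `mu0` and the returned
#' p-value is 0 (all values differ from mu0) or 1 (all equal), flagged via
#' `degenerate = TRUE`.
#'
#' @param x Numeric vector, n >= 2.
#' @param y Optional second sample (two-sample Welch mode).
#' @param mu0 Null mean for the one-sample mode (default 0).
#' @return List with `t`, `df`, `p`, `estimate`, and `degenerate` flag.
#' @export
welch_t <- function(x, y = NULL, mu0 = 0) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("each sample needs n >= 2")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) < 2L) stop("each sample needs n >= 2")
    m <- length(x); n <- length(y)
    vx <- stats::var(x) / m; vy <- stats::var(y) / n
    se2 <- vx + vy
    if (se2 == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(list(t = if (eq) 0 else Inf, df = m + n - 2,
                  p = if (eq) 1 else 0,
                  estimate = mean(x) - mean(y), degenerate = TRUE))
    }
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (m - 1) + vy^2 / (n - 1))
    list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
         estimate = mean(x) - mean(y), degenerate = FALSE)
  } else {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) {
      eq <- isTRUE(all.equal(mean(x), mu0))
      return(list(t = if (eq) 0 else Inf * sign(mean(x) - mu0), df = n - 1,
                  p = if (eq) 1 else 0, estimate = mean(x), degenerate = TRUE))
    }
    tstat <- (mean(x) - mu0) / (s / sqrt(n))
    list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1),
         estimate = mean(x), degenerate = FALSE)
  }
}

#' F-test for equality of variances
#'
#' Two-sided variance-ratio test used to decide whether Welch's correction
#' is warranted before a two-sample comparison.
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @return List with `F` (var(x)/var(y)), `df1`, `df2`, `p`.
#' @export
var_f_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  vy <- stats::var(y)
  if (vy == 0) stop("variance of y is zero; F undefined")
  Fstat <- stats::var(x) / vy
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  pl <- stats::pf(Fstat, df1, df2)
  p <- 2 * min(pl, 1 - pl)
  list(F = Fstat, df1 = df1, df2 = df2, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' Order-preserving: adjusted values are returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`; each adjusted
#'   value is >= its raw value.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}
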