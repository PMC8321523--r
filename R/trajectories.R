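## Persister-fraction estimation and sigmoidal adaptation-trajectory
## fitting. The adaptation curve of log10 persister fractions over cycles
## is fitted with the four-parameter logistic
##   p(t) = L + (U - L) / (1 + exp(-S (t - lambda))),
## where S is the steepness (rate of adaptation) and lambda the lag before
## adaptation. Fixing (L, U) = (0, 1) recovers the strict two-parameter
## sigmoid for inputs already normalized to (0, 1).

#' Persister fraction from CFU counts
#'
#' Survival fraction of a fixed-duration bactericidal treatment:
#' CFU after treatment divided by CFU before.
#'
#' A fraction above 1 (apparent growth during treatment) is reported as-is
#' with a warning, not clamped. A sterile outcome (0 survivors) returns 0
#' with attribute `sterile = TRUE`.
#'
#' @param cfu_before CFU/ml before treatment (> 0).
#' @param cfu_after CFU/ml after treatment (>= 0).
#' @return The fraction `cfu_after / cfu_before`.
#' @examples
#' persister_fraction(2e8, 3e4)  # 1.5e-4
#' @export
persister_fraction <- function(cfu_before, cfu_after) {
  if (!is.finite(cfu_before) || cfu_before <= 0)
    stop("cfu_before must be > 0")
  if (!is.finite(cfu_after) || cfu_after < 0)
    stop("cfu_after must be >= 0")
  f <- cfu_after / cfu_before
  if (f > 1) warning("persister fraction > 1: more CFU after treatment than before")
  if (cfu_after == 0) return(structure(0, sterile = TRUE))
  f
}

#' log10 persister fraction with half-detection-limit substitution
#'
#' Zero survivor counts cannot be log-transformed; they are replaced by
#' half a detection limit of one colony, `log10(0.5 / cfu_before)`, and
#' flagged via the `censored` attribute.
#'
#' @param cfu_before,cfu_after CFU/ml vectors (before > 0, after >= 0).
#' @return log10 fractions with logical attribute `censored`.
#' @export
log10_persister_fraction <- function(cfu_before, cfu_after) {
  if (any(cfu_before <= 0)) stop("cfu_before must be > 0")
  if (any(cfu_after < 0)) stop("cfu_after must be >= 0")
  censored <- cfu_after == 0
  f <- ifelse(censored, 0.5 / cfu_before, cfu_after / cfu_before)
  structure(log10(f), censored = censored)
}

# Variable-projection RSS: for fixed (S, lambda) the model is linear in
# (L, U) through z = 1/(1 + exp(-S (t - lambda))). Returns the profiled
# linear solution and RSS.
.sigmoid_profile <- function(S, lam, t, p) {
  z <- 1 / (1 + exp(-S * (t - lam)))
  X <- cbind(1 - z, z)                       # p = L (1 - z) + U z
  fit <- tryCatch(stats::lm.fit(X, p), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(list(rss = Inf, L = NA_real_, U = NA_real_))
  list(rss = sum(fit$residuals^2),
       L = unname(fit$coefficients[1]), U = unname(fit$coefficients[2]))
}

.sigmoid_pred <- function(par, t) {
  par[["L"]] + (par[["U"]] - par[["L"]]) /
    (1 + exp(-par[["S"]] * (t - par[["lam"]])))
}

.sigmoid_fit_core <- function(t, p, fix_asymptotes = NULL) {
  # coarse grid over (S, lambda) with analytically profiled (L, U)
  S_grid <- exp(seq(log(0.2), log(5), length.out = 12))
  S_grid <- c(S_grid, -S_grid)               # allow decreasing trajectories
  lam_grid <- seq(min(t), max(t), length.out = 15)
  best <- list(rss = Inf)
  for (S in S_grid) for (lam in lam_grid) {
    if (is.null(fix_asymptotes)) {
      pr <- .sigmoid_profile(S, lam, t, p)
      if (pr$rss < best$rss)
        best <- list(rss = pr$rss, S = S, lam = lam, L = pr$L, U = pr$U)
    } else {
      pred <- fix_asymptotes[1] + diff(fix_asymptotes) /
        (1 + exp(-S * (t - lam)))
      rss <- sum((p - pred)^2)
      if (rss < best$rss)
        best <- list(rss = rss, S = S, lam = lam,
                     L = fix_asymptotes[1], U = fix_asymptotes[2])
    }
  }
  # quasi-Newton polish of all free parameters from the best grid point
  if (is.null(fix_asymptotes)) {
    obj <- function(th) {
      pred <- th[1] + (th[2] - th[1]) / (1 + exp(-th[3] * (t - th[4])))
      sum((p - pred)^2)
    }
    start <- c(best$L, best$U, best$S, best$lam)
    opt <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value <= best$rss + 1e-12)
      best <- list(rss = opt$value, L = opt$par[1], U = opt$par[2],
                   S = opt$par[3], lam = opt$par[4])
  } else {
    obj <- function(th) {
      pred <- fix_asymptotes[1] + diff(fix_asymptotes) /
        (1 + exp(-th[1] * (t - th[2])))
      sum((p - pred)^2)
    }
    opt <- tryCatch(
      stats::optim(c(best$S, best$lam), obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value <= best$rss + 1e-12)
      best <- list(rss = opt$value, S = opt$par[1], lam = opt$par[2],
                   L = fix_asymptotes[1], U = fix_asymptotes[2])
  }
  # canonical orientation: report U >= L (flip S if needed)
  if (best$U < best$L) {
    tmp <- best$L; best$L <- best$U; best$U <- tmp
    best$S <- -best$S
  }
  best
}

#' Fit the sigmoidal adaptation trajectory
#'
#' Least-squares fit of the four-parameter logistic
#' `p(t) = L + (U - L) / (1 + exp(-S (t - lambda)))` to log10 persister
#' fractions over cycles. S (per cycle) is the rate of adaptation and
#' lambda (cycles) the lag before adaptation; L and U are the lower and
#' upper asymptotes on the log10 scale. Passing
#' `fix_asymptotes = c(0, 1)` fits the strict two-parameter sigmoid for
#' trajectories pre-normalized into (0, 1).
#'
#' Fitting uses a (S, lambda) grid with analytically profiled asymptotes
#' followed by a BFGS polish. Confidence intervals are by residual
#' bootstrap. Flat (constant) data leave S unidentifiable and return
#' `converged = FALSE` rather than a silent answer.
#'
#' @param t Cycle numbers, strictly increasing, >= 5 points.
#' @param p log10 persister fractions (or normalized values), same length.
#' @param fix_asymptotes Optional `c(L, U)` to hold the asymptotes fixed.
#' @param n_boot Bootstrap resamples for 95% CIs (default 200; 0 skips).
#' @param boot_seed Seed for the bootstrap (default 1).
#' @return An object of class `"trajectory_fit"`: list with `S`, `lam`,
#'   `L`, `U`, `rss`, `converged`, `ci` (parameter x (lo, hi) matrix or
#'   NULL), `t`, `p`, `fitted`, `diagnostic`.
#' @export
fit_adaptation_sigmoid <- function(t, p, fix_asymptotes = NULL,
                                   n_boot = 200L, boot_seed = 1L) {
  t <- as.numeric(t); p <- as.numeric(p)
  if (length(t) != length(p)) stop("t and p must have equal length")
  if (length(t) < 5L) stop("need >= 5 points to fit four parameters")
  if (any(diff(t) < 0)) stop("t must be nondecreasing")
  if (length(unique(t)) < 5L) stop("need >= 5 distinct time points")
  if (!is.null(fix_asymptotes)) {
    stopifnot(length(fix_asymptotes) == 2, fix_asymptotes[2] > fix_asymptotes[1])
  }

  if (stats::sd(p) < 1e-10) {
    return(structure(list(S = NA_real_, lam = NA_real_,
                          L = mean(p), U = mean(p), rss = 0,
                          converged = FALSE, ci = NULL, t = t, p = p,
                          fitted = rep(mean(p), length(p)),
                          diagnostic = "flat data: steepness unidentifiable"),
                     class = "trajectory_fit"))
  }

  best <- .sigmoid_fit_core(t, p, fix_asymptotes)
  par <- c(L = unname(best$L), U = unname(best$U),
           S = unname(best$S), lam = unname(best$lam))
  fitted <- .sigmoid_pred(par, t)
  converged <- is.finite(best$rss) && all(is.finite(par))

  ci <- NULL
  if (converged && n_boot > 0) {
    res <- p - fitted
    boot <- matrix(NA_real_, n_boot, 4,
                   dimnames = list(NULL, c("L", "U", "S", "lam")))
    old <- .save_rng()
    set.seed(boot_seed)
    for (b in seq_len(n_boot)) {
      pb <- fitted + sample(res, replace = TRUE)
      fb <- tryCatch(.sigmoid_fit_core(t, pb, fix_asymptotes),
                     error = function(e) NULL)
      if (!is.null(fb)) boot[b, ] <- c(fb$L, fb$U, fb$S, fb$lam)
    }
    .restore_rng(old)
    ci <- base::t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                        na.rm = TRUE))
    colnames(ci) <- c("lo", "hi")
  }

  structure(list(S = unname(best$S), lam = unname(best$lam),
                 L = unname(best$L), U = unname(best$U),
                 rss = best$rss, converged = converged, ci = ci,
                 t = t, p = p, fitted = fitted, diagnostic = "ok"),
            class = "trajectory_fit")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.trajectory_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Adaptation trajectory fit: NOT converged -", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("Adaptation trajectory fit (n = %d)\n", length(x$t)))
  cat(sprintf("  S = %.4g per cycle, lambda = %.4g cycles\n", x$S, x$lam))
  cat(sprintf("  asymptotes: L = %.4g, U = %.4g (log10), RSS = %.4g\n",
              x$L, x$U, x$rss))
  invisible(x)
}

#' Summarize adaptation across bottleneck regimes
#'
#' Groups per-population trajectory fits by dilution ratio and reports, per
#' group: mean steepness S, mean lag lambda, the log10 fold-increase
#' `U - L`, and the across-population variance of the final log10 persister
#' fraction. A Spearman rank test of S against D quantifies whether the
#' rate of adaptation increases with bottleneck size.
#'
#' @param fits List of converged [fit_adaptation_sigmoid()] results.
#' @param D Dilution ratio of each fit's population (same length).
#' @param final_p Final-cycle log10 persister fraction of each population;
#'   default the last fitted observation.
#' @return List with `summary` (one row per D) and `spearman_S_vs_D`
#'   (a [spearman_exact()] test of group-mean S against D).
#' @export
adaptation_summary <- function(fits, D, final_p = NULL) {
  stopifnot(length(fits) == length(D))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warning(sprintf("dropping %d non-converged fit(s)", sum(!conv)))
    fits <- fits[conv]; D <- D[conv]
    if (!is.null(final_p)) final_p <- final_p[conv]
  }
  if (length(unique(D)) < 2L) stop("need >= 2 bottleneck groups")
  if (is.null(final_p))
    final_p <- vapply(fits, function(f) f$p[length(f$p)], numeric(1))
  S <- vapply(fits, `[[`, numeric(1), "S")
  lam <- vapply(fits, `[[`, numeric(1), "lam")
  span <- vapply(fits, function(f) f$U - f$L, numeric(1))
  grp <- sort(unique(D))
  summ <- do.call(rbind, lapply(grp, function(d) {
    i <- D == d
    data.frame(D = d, n = sum(i), mean_S = mean(S[i]),
               mean_lambda = mean(lam[i]), mean_log10_fold = mean(span[i]),
               var_final_log10 = if (sum(i) > 1) stats::var(final_p[i])
                                 else NA_real_)
  }))
  sp <- if (stats::sd(summ$mean_S) > 0) spearman_exact(summ$D, summ$mean_S)
        else NULL  # identical trajectories: correlation undefined
  list(summary = summ, spearman_S_vs_D = sp)
}
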