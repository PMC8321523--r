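## Analytics for barcoded knockout-library selections: control-design
## normalization (median-of-ratios restricted to inert designs),
## enrichment/depletion calls on replicate log2 fold-changes with
## growth-control filtering, and the diversity / between-replicate
## heterogeneity metrics.

#' Barcode count table
#'
#' Designs-by-samples integer read counts from barcode amplicon sequencing,
#' with design metadata (control flags) and sample metadata (replicate,
#' bottleneck, before/after timepoint, selection vs growth-control arm).
#'
#' @param counts Numeric matrix (designs x samples) of nonnegative integer
#'   read counts with design ids as rownames and sample ids as colnames.
#' @param design_meta Data frame with at least `id` and `is_control`,
#'   one row per design in row order of `counts`.
#' @param sample_meta Data frame with at least `sample_id`, `replicate`,
#'   `timepoint` (`"before"`/`"after"`); one row per column of `counts`.
#' @return An object of class `"barcode_count_table"`.
#' @export
barcode_count_table <- function(counts, design_meta, sample_meta) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be nonnegative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  stopifnot(is.data.frame(design_meta),
            all(c("id", "is_control") %in% names(design_meta)),
            nrow(design_meta) == nrow(counts),
            is.data.frame(sample_meta),
            all(c("sample_id", "replicate", "timepoint") %in%
                  names(sample_meta)),
            nrow(sample_meta) == ncol(counts))
  if (!all(sample_meta$timepoint %in% c("before", "after")))
    stop("timepoint must be 'before' or 'after'")
  rownames(counts) <- design_meta$id
  colnames(counts) <- sample_meta$sample_id
  structure(list(counts = counts, design_meta = design_meta,
                 sample_meta = sample_meta),
            class = "barcode_count_table")
}

#' @export
print.barcode_count_table <- function(x, ...) {
  cat(sprintf("Barcode count table: %d designs (%d controls) x %d samples\n",
              nrow(x$counts), sum(x$design_meta$is_control), ncol(x$counts)))
  invisible(x)
}

#' Control-design median-of-ratios normalization
#'
#' Per-sample size factors computed from the inert control designs only
#' (mirroring normalization against silent/inert constructs): for each
#' control, the ratio of its count to its geometric mean across samples;
#' the size factor is the per-sample median of these ratios, rescaled to
#' geometric mean 1 so that normalization is idempotent. Normalized count =
#' raw count / size factor.
#'
#' Controls with a zero count in any sample have no finite geometric-mean
#' ratio and are dropped with a warning; at least one usable control must
#' remain.
#'
#' @param table A [barcode_count_table()] with >= 1 control design.
#' @return List with `table` (normalized counts, same structure) and
#'   `size_factors` (named per-sample vector).
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "barcode_count_table"))
  ctrl <- table$counts[table$design_meta$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control designs available for normalization")
  usable <- rowSums(ctrl == 0) == 0
  if (any(!usable)) {
    warning(sprintf("dropping %d control design(s) with zero counts",
                    sum(!usable)))
    ctrl <- ctrl[usable, , drop = FALSE]
  }
  if (nrow(ctrl) == 0) stop("no usable control designs (all contain zeros)")
  log_gm <- rowMeans(log(ctrl))
  ratios <- exp(sweep(log(ctrl), 1, log_gm))           # count / geomean
  sf <- apply(ratios, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))                        # geometric mean 1
  out <- table
  out$counts <- sweep(table$counts, 2, sf, "/")
  list(table = out, size_factors = stats::setNames(sf, colnames(table$counts)))
}

#' Per-design log2 fold-change
#'
#' `log2((after + pseudocount) / (before + pseudocount))`, elementwise on
#' matched before/after counts (raw or normalized).
#'
#' @param before,after Nonnegative count vectors or matrices of matching
#'   shape.
#' @param pseudocount Stabilizing pseudocount (default 0.5).
#' @return log2 fold-changes, same shape as the inputs.
#' @export
log2_fold_change <- function(before, after, pseudocount = 0.5) {
  if (length(before) != length(after))
    stop("before and after must be matched")
  if (any(before < 0) || any(after < 0)) stop("counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log2((after + pseudocount) / (before + pseudocount))
}

# Extract the per-replicate log2 fold-change matrix (designs x replicates)
# from a barcode count table, optionally after normalization.
#' Replicate log2 fold-change matrix from a count table
#'
#' Matches each replicate's before/after samples and returns the
#' designs-by-replicates matrix of log2 fold-changes.
#'
#' @param table A [barcode_count_table()].
#' @param normalize Normalize with [normalize_counts()] first (default
#'   TRUE).
#' @param pseudocount Passed to [log2_fold_change()].
#' @return Matrix of log2 fold-changes (designs x replicates).
#' @export
replicate_lfc <- function(table, normalize = TRUE, pseudocount = 0.5) {
  stopifnot(inherits(table, "barcode_count_table"))
  if (normalize) table <- normalize_counts(table)$table
  sm <- table$sample_meta
  reps <- sort(unique(sm$replicate))
  lfc <- sapply(reps, function(r) {
    b <- which(sm$replicate == r & sm$timepoint == "before")
    a <- which(sm$replicate == r & sm$timepoint == "after")
    if (length(b) != 1L || length(a) != 1L)
      stop(sprintf("replicate %s lacks a matched before/after pair", r))
    log2_fold_change(table$counts[, b], table$counts[, a], pseudocount)
  })
  dimnames(lfc) <- list(table$design_meta$id, paste0("rep", reps))
  lfc
}

#' Enrichment/depletion test on replicate log2 fold-changes
#'
#' Per design, a two-sided one-sample t-test of the replicate log2
#' fold-changes against 0, Benjamini-Hochberg adjusted across designs; a
#' design is called `enriched`/`depleted` by the sign of its mean when the
#' adjusted p falls below `alpha`. Designs with zero replicate variance are
#' handled by an exact sign-flip permutation fallback (p = 2/2^n when all
#' replicates share a nonzero value).
#'
#' @param lfc Matrix of log2 fold-changes (designs x replicates, >= 3
#'   replicates) as from [replicate_lfc()].
#' @param alpha Significance level after adjustment (default 0.05).
#' @return Data frame of class `"enrichment_result"`: `design_id`, `mean_lfc`,
#'   `p`, `padj`, `call` in {enriched, depleted, none}, `growth_confounded`
#'   (initialized FALSE).
#' @export
enrichment_test <- function(lfc, alpha = 0.05) {
  lfc <- as.matrix(lfc)
  if (ncol(lfc) < 3L) stop("need >= 3 replicates per design")
  m <- rowMeans(lfc)
  s <- apply(lfc, 1, stats::sd)
  n <- ncol(lfc)
  p <- numeric(nrow(lfc))
  ok <- s > 0
  tstat <- m[ok] / (s[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1)
  if (any(!ok)) {
    # all replicates identical: exact two-sided sign-flip permutation
    p[!ok] <- ifelse(m[!ok] == 0, 1, 2 / 2^n)
  }
  padj <- bh_adjust(p)
  call <- rep("none", nrow(lfc))
  sig <- padj < alpha
  call[sig & m > 0] <- "enriched"
  call[sig & m < 0] <- "depleted"
  out <- data.frame(design_id = rownames(lfc), mean_lfc = m, p = p,
                    padj = padj, call = call, growth_confounded = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter growth-confounded hits against the growth-only control arm
#'
#' Designs that are significant in the growth-only control experiment are
#' flagged `growth_confounded` and have their selection-arm call reset to
#' `"none"`: their count change is explained by altered growth rather than
#' altered antibiotic tolerance.
#'
#' @param selection [enrichment_test()] results from the selection arm.
#' @param control [enrichment_test()] results from the growth-only arm;
#'   must cover the identical design set.
#' @return The filtered selection results.
#' @export
filter_growth_confounded <- function(selection, control) {
  if (!setequal(selection$design_id, control$design_id) ||
      nrow(selection) != nrow(control))
    stop("selection and control results must cover the same designs")
  ctrl_sig <- control$design_id[control$call != "none"]
  hit <- selection$design_id %in% ctrl_sig
  selection$growth_confounded <- hit
  selection$call[hit] <- "none"
  selection
}

#' Library diversity after selection
#'
#' Per after-selection sample: the retained-design fraction (share of
#' designs with raw read count >= `threshold`, the lost-mutant rule) and
#' the within-population design-frequency distribution as a log10-frequency
#' histogram.
#'
#' @param table A [barcode_count_table()] (raw counts).
#' @param threshold Minimum raw read count to call a design retained
#'   (default 3).
#' @param breaks Histogram breaks on log10 frequency (default
#'   `seq(-8, 0, 0.5)`).
#' @return List with `retained` (data frame: sample_id, replicate,
#'   retained_fraction) and `freq_hist` (per sample, counts of designs per
#'   log10-frequency bin; zero-count designs are excluded from the
#'   histogram). An empty (all-zero) sample has `NA` retained fraction and
#'   is flagged with a warning.
#' @export
diversity_metrics <- function(table, threshold = 3, breaks = seq(-8, 0, 0.5)) {
  stopifnot(inherits(table, "barcode_count_table"))
  after <- which(table$sample_meta$timepoint == "after")
  if (length(after) == 0) stop("no after-selection samples present")
  cts <- table$counts[, after, drop = FALSE]
  tot <- colSums(cts)
  if (any(tot == 0)) warning("empty after-selection sample(s): retained fraction undefined")
  retained <- ifelse(tot > 0, colMeans(cts >= threshold), NA_real_)
  freq_hist <- lapply(seq_along(after), function(j) {
    if (tot[j] == 0) return(NULL)
    f <- cts[, j] / tot[j]
    lf <- log10(f[f > 0])
    lf <- pmin(pmax(lf, breaks[1]), breaks[length(breaks)])
    tabulate(cut(lf, breaks, include.lowest = TRUE),
             nbins = length(breaks) - 1L)
  })
  names(freq_hist) <- colnames(cts)
  list(retained = data.frame(
         sample_id = colnames(cts),
         replicate = table$sample_meta$replicate[after],
         retained_fraction = unname(retained),
         stringsAsFactors = FALSE),
       freq_hist = freq_hist, breaks = breaks)
}

#' Between-replicate heterogeneity of selection outcomes
#'
#' All pairwise Pearson correlations of raw after-selection count vectors
#' across replicate populations (constant or empty vectors are excluded
#' with a warning), their mean, and a tally of the top design per
#' population: the design with the largest |log2 fold-change| on raw
#' counts. Ties are broken by the smallest design id and flagged.
#'
#' @param table A [barcode_count_table()] with >= 2 replicates (raw counts).
#' @param pseudocount Pseudocount for the raw-count fold-change (default
#'   0.5).
#' @param log_counts Correlate log10(count + 1) instead of raw counts
#'   (default FALSE; the headline analysis uses raw counts).
#' @return List with `pearson` (replicate x replicate matrix), `mean_r`,
#'   `top_hits` (data frame: replicate, design_id, tied flag) and
#'   `top_tally` (named tally over designs).
#' @export
heterogeneity_metrics <- function(table, pseudocount = 0.5,
                                  log_counts = FALSE) {
  stopifnot(inherits(table, "barcode_count_table"))
  sm <- table$sample_meta
  reps <- sort(unique(sm$replicate))
  if (length(reps) < 2L) stop("need >= 2 replicate populations")
  after <- sapply(reps, function(r)
    which(sm$replicate == r & sm$timepoint == "after")[1])
  cts <- table$counts[, after, drop = FALSE]
  if (log_counts) cts <- log10(cts + 1)
  usable <- apply(cts, 2, function(v) stats::sd(v) > 0)
  if (any(!usable))
    warning(sprintf("%d replicate(s) with constant counts excluded from correlations",
                    sum(!usable)))
  pear <- matrix(NA_real_, length(reps), length(reps),
                 dimnames = list(paste0("rep", reps), paste0("rep", reps)))
  diag(pear) <- 1
  if (sum(usable) >= 2) {
    sub <- stats::cor(cts[, usable, drop = FALSE])
    pear[usable, usable] <- sub
  }
  off <- pear[upper.tri(pear)]
  mean_r <- mean(off, na.rm = TRUE)

  lfc <- replicate_lfc(table, normalize = FALSE, pseudocount = pseudocount)
  top <- lapply(seq_along(reps), function(i) {
    v <- abs(lfc[, i])
    mx <- max(v)
    cand <- sort(rownames(lfc)[v == mx])
    data.frame(replicate = reps[i], design_id = cand[1],
               tied = length(cand) > 1, stringsAsFactors = FALSE)
  })
  top <- do.call(rbind, top)
  list(pearson = pear, mean_r = mean_r, top_hits = top,
       top_tally = sort(base::table(top$design_id), decreasing = TRUE))
}

#' Top-variant tally from a variant-frequency table
#'
#' For whole-genome variant data: in each population, which variant (or
#' operon) attained the highest frequency. Ties are broken by the smallest
#' id and flagged.
#'
#' @param variants Data frame with columns `population_id`, `variant_id`,
#'   `gene`, `operon`, `frequency` (in \[0, 1\]).
#' @param by Group winners by `"variant"` (default) or `"operon"`.
#' @return List with `top_hits` (population_id, id, frequency, tied) and
#'   `top_tally` (named tally, decreasing).
#' @export
top_variant_tally <- function(variants, by = c("variant", "operon")) {
  by <- match.arg(by)
  req <- c("population_id", "variant_id", "gene", "operon", "frequency")
  stopifnot(is.data.frame(variants), all(req %in% names(variants)))
  if (any(variants$frequency < 0 | variants$frequency > 1))
    stop("frequencies must lie in [0, 1]")
  key <- if (by == "variant") variants$variant_id else variants$operon
  pops <- unique(variants$population_id)
  top <- lapply(pops, function(p) {
    sub <- variants$population_id == p
    f <- variants$frequency[sub]
    mx <- max(f)
    cand <- sort(unique(key[sub][f == mx]))
    data.frame(population_id = p, id = cand[1], frequency = mx,
               tied = length(cand) > 1, stringsAsFactors = FALSE)
  })
  top <- do.call(rbind, top)
  list(top_hits = top, top_tally = sort(table(top$id), decreasing = TRUE))
}
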