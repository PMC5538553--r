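#' Midpoint overlap count
#'
#' Number of query intervals (CRSs) whose midpoint `floor((start + end) / 2)`
#' falls inside any feature interval (0-based half-open containment; strand
#' ignored).
#'
#' @param crs,features [interval_set] objects.
#' @return Integer count `q`.
#' @export
overlap_count <- function(crs, features) {
  sum(midpoint_in_features(crs, features))
}

midpoint_in_features <- function(crs, features) {
  if (nrow(crs) == 0L) return(logical(0))
  hit <- logical(nrow(crs))
  if (nrow(features) == 0L) return(hit)
  mid <- (crs$start + crs$end) %/% 2L
  for (chr in unique(crs$chrom)) {
    ci <- which(crs$chrom == chr)
    fi <- which(features$chrom == chr)
    if (length(fi) == 0L) next
    q <- IRanges::IRanges(mid[ci] + 1L, mid[ci] + 1L)
    f <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    hit[ci] <- IRanges::overlapsAny(q, f)
  }
  hit
}

#' One-sided Z-test for interval enrichment
#'
#' Normal approximation to the binomial: with `n` query intervals and
#' background overlap probability `p`, the observed overlap count `q` yields
#' \eqn{z = (q - np)/\sqrt{np(1-p)}} and the upper-tail standard-normal
#' p-value.  When the feature coverage of the tested bin is provided and
#' totals less than `min_coverage` bases the statistic is refused (`NA`).
#'
#' @param q observed overlap count.
#' @param n number of query intervals (>= 1).
#' @param p background overlap probability, in (0, 1).
#' @param coverage optional feature base coverage of the bin.
#' @param min_coverage minimum coverage in bases (default 1000).
#' @return List with `z` and `pvalue` (both `NA` with a `reason` when
#'   refused).
#' @export
enrichment_ztest <- function(q, n, p, coverage = NULL, min_coverage = 1000) {
  if (n < 1) stop("n must be >= 1")
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)")
  if (!is.null(coverage) && coverage < min_coverage)
    return(list(z = NA_real_, pvalue = NA_real_,
                reason = sprintf("feature coverage %d b < %d b",
                                 as.integer(coverage), as.integer(min_coverage))))
  z <- (q - n * p) / sqrt(n * p * (1 - p))
  list(z = z, pvalue = pnorm(z, lower.tail = FALSE))
}

#' Fold enrichment
#'
#' `fe = q / (n * p)`: observed over expected overlap count.
#'
#' @inheritParams enrichment_ztest
#' @return Fold enrichment.
#' @export
fold_enrichment <- function(q, n, p) {
  if (p <= 0) stop("p must be > 0")
  q / (n * p)
}

#' GC/SI-stratified interval enrichment
#'
#' The enrichment test stratified over a grid of (GC content, sequence
#' identity) bins of fixed-width genome windows: each query interval is
#' assigned the bin of the window containing its midpoint; each bin's
#' background probability `p` is the fraction of the bin's window bases
#' covered by the (merged) feature set; a one-sided Z-test is run per bin and
#' Benjamini-Hochberg correction applied across the bins of the grid.  Bins
#' whose feature coverage is below 1 kb are reported with `NA` statistics;
#' empty bins are skipped.
#'
#' @param crs [interval_set] of query intervals (e.g. CRSs).
#' @param features [interval_set] of annotation features.
#' @param windows a [genome_windows()] grid with `gc` and `si` columns.
#' @param gc_bins,si_bins bin boundaries for GC and SI (defaults: GC
#'   `c(0, .2, .4, .65, .8, 1)`, SI `c(0, .5, .7, .9, 1)`).
#' @param min_coverage minimum per-bin feature coverage in bases.
#' @return Data frame with one row per non-empty bin: `gc_bin`, `si_bin`,
#'   `q`, `n`, `p`, `coverage`, `z`, `pvalue`, `qvalue`, `fe`.
#' @export
stratified_enrichment <- function(crs, features, windows,
                                  gc_bins = c(0, 0.2, 0.4, 0.65, 0.8, 1),
                                  si_bins = c(0, 0.5, 0.7, 0.9, 1),
                                  min_coverage = 1000) {
  features <- merge_intervals(features)
  wgc <- cut(windows$gc, gc_bins, include.lowest = TRUE)
  wsi <- cut(windows$si, si_bins, include.lowest = TRUE)
  # feature coverage per window
  cov <- numeric(nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    fi <- which(features$chrom == chr)
    if (length(fi) == 0L) next
    w <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    f <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    ov <- IRanges::findOverlaps(w, f)
    if (length(ov) == 0L) next
    inter <- IRanges::pintersect(w[S4Vectors::queryHits(ov)],
                                 f[S4Vectors::subjectHits(ov)])
    widths <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    cov[wi[as.integer(names(widths))]] <- as.numeric(widths)
  }
  # window of each query midpoint
  widx <- rep(NA_integer_, nrow(crs))
  mid <- (crs$start + crs$end) %/% 2L
  for (chr in unique(crs$chrom)) {
    ci <- which(crs$chrom == chr)
    wi <- which(windows$chrom == chr)
    if (length(wi) == 0L) next
    q <- IRanges::IRanges(mid[ci] + 1L, mid[ci] + 1L)
    w <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(q, w, select = "first")
    widx[ci] <- wi[ov]
  }
  in_feat <- midpoint_in_features(crs, features)
  rows <- list()
  for (g in levels(wgc)) for (s in levels(wsi)) {
    wbin <- which(wgc == g & wsi == s)
    if (length(wbin) == 0L) next
    cbin <- which(!is.na(widx) & widx %in% wbin)
    n <- length(cbin)
    if (n == 0L) next   # empty bin: skipped
    binbases <- sum(windows$end[wbin] - windows$start[wbin])
    bincov <- sum(cov[wbin])
    p <- bincov / binbases
    q <- sum(in_feat[cbin])
    if (bincov < min_coverage || p <= 0 || p >= 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        gc_bin = g, si_bin = s, q = q, n = n, p = p, coverage = bincov,
        z = NA_real_, pvalue = NA_real_, fe = NA_real_)
      next
    }
    zt <- enrichment_ztest(q, n, p, coverage = bincov,
                           min_coverage = min_coverage)
    rows[[length(rows) + 1L]] <- data.frame(
      gc_bin = g, si_bin = s, q = q, n = n, p = p, coverage = bincov,
      z = zt$z, pvalue = zt$pvalue, fe = fold_enrichment(q, n, p))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$qvalue <- NA_real_
  ok <- !is.na(out$pvalue)
  out$qvalue[ok] <- bh_correct(out$pvalue[ok])
  out
}

#' Fisher's exact test for conserved-site contingency tables
#'
#' One-sided (enrichment direction) exact hypergeometric test on the 2x2
#' table, e.g. CRS conservation versus binding-site conservation.  The odds
#' ratio is the sample odds ratio `ad / bc` (`Inf` when `bc = 0`).
#'
#' @param a,b,c,d non-negative counts, or a 2x2 matrix passed as `a`.
#' @return List with `odds_ratio` and `pvalue`.
#' @export
conserved_site_fet <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero contingency table")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  pv <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  list(odds_ratio = or, pvalue = pv)
}

#' Purifying-selection ratio rule
#'
#' Selection ratios of a query distance against ancestral-repeat and
#' intergenic control distances.  Purifying selection is called when both
#' ratios are below 0.95.
#'
#' @param d_crs pairwise distance within the query (e.g. a CRS alignment).
#' @param d_ar distance in nearby ancestral repeats (> 0).
#' @param d_inter distance in nearby intergenic loci (> 0).
#' @param cutoff ratio cutoff (default 0.95).
#' @return List with `r1 = d_crs/d_ar`, `r2 = d_crs/d_inter`, `purifying`.
#' @export
selection_ratio <- function(d_crs, d_ar, d_inter, cutoff = 0.95) {
  if (d_ar <= 0 || d_inter <= 0) stop("control distances must be > 0")
  if (d_crs < 0) stop("distances must be >= 0")
  r1 <- d_crs / d_ar
  r2 <- d_crs / d_inter
  list(r1 = r1, r2 = r2, purifying = (r1 < cutoff && r2 < cutoff))
}

#' Benjamini-Hochberg correction
#'
#' Standard step-up q-values; applied within one analysis family (one feature
#' set and bin grid).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
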