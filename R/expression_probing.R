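#' Empirical p-value of a read count
#'
#' Rank-based p-value of an observed count against a background count
#' distribution (random genomic loci, or off-target read islands), with
#' add-one smoothing so p is never 0:
#' `p = (1 + #\{b >= observed\}) / (1 + |background|)`.
#'
#' @param observed observed count (scalar or vector).
#' @param background numeric vector of background counts (non-empty).
#' @return Empirical p-value(s) in (0, 1].
#' @export
empirical_pvalue <- function(observed, background) {
  if (length(background) == 0L) stop("empty background")
  vapply(observed, function(o)
    (1 + sum(background >= o)) / (1 + length(background)), numeric(1))
}

#' Expression calls from counts and a background distribution
#'
#' @param counts named vector of per-feature read counts.
#' @param background background counts (see [empirical_pvalue()]).
#' @param p_cutoff call cutoff; features with `p < p_cutoff` are "expressed"
#'   (default 0.01).
#' @return Data frame with `feature`, `count`, `empirical_p`, `expressed`.
#' @export
expression_calls <- function(counts, background, p_cutoff = 0.01) {
  p <- empirical_pvalue(counts, background)
  data.frame(feature = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             count = as.numeric(counts), empirical_p = p,
             expressed = p < p_cutoff, row.names = NULL)
}

#' 201-bp expression windows around interval midpoints
#'
#' Helper building the fixed windows in which expression of a region is
#' quantified: a `width`-bp window centred on each interval's midpoint.
#'
#' @param regions an [interval_set].
#' @param width window width (default 201).
#' @return An [interval_set] of windows (clipped at coordinate 0).
#' @export
expression_windows <- function(regions, width = 201) {
  mid <- (regions$start + regions$end) %/% 2L
  half <- width %/% 2L
  interval_set(regions$chrom, pmax(mid - half, 0L), mid + half + 1L,
               name = regions$name, strand = regions$strand)
}

#' CPM with relative log expression (RLE) normalization
#'
#' Median-of-ratios size factors: for every feature with all-positive counts
#' the ratio of each sample's count to the feature's geometric mean is taken,
#' and a sample's size factor is the median of its ratios.  Normalized values
#' are counts per million of the effective library size:
#' `count / (library_size * size_factor) * 1e6`.
#'
#' @param m integer matrix, features x samples (>= 2 samples).
#' @return List with `size_factors`, `normalized` (CPM/RLE matrix) and the
#'   input `counts`.
#' @export
cpm_rle_normalize <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 samples")
  if (any(m < 0)) stop("counts must be non-negative")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no feature has positive counts in all samples")
  logg <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col)
    median(exp(log(col) - logg)))
  lib <- colSums(m)
  norm <- sweep(m, 2, lib * sf, "/") * 1e6
  list(size_factors = sf, normalized = norm, counts = m)
}

#' Cross-species coexpression
#'
#' Pearson correlation of two expression profiles over matched tissues, with
#' a "strong coexpression" flag at `r >= strong_cutoff`.
#'
#' @param profile_a,profile_b numeric vectors of equal length >= 3.
#' @param strong_cutoff correlation cutoff for the strong flag (default 0.8).
#' @return List with `r` and `strong` (`NA` when either profile has zero
#'   variance).
#' @export
coexpression <- function(profile_a, profile_b, strong_cutoff = 0.8) {
  if (length(profile_a) != length(profile_b) || length(profile_a) < 3L)
    stop("profiles must have equal length >= 3")
  if (sd(profile_a) == 0 || sd(profile_b) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(list(r = NA_real_, strong = NA))
  }
  r <- cor(profile_a, profile_b)
  list(r = r, strong = r >= strong_cutoff)
}

#' Call read islands from stranded reads
#'
#' Targeted-capture island calling: (1) reads overlapping simple repeats by
#' at least half their length are removed; (2) each read is replaced by a
#' fixed `extension`-nt interval anchored at its 5' end in reading direction
#' (a "unified read"); (3) overlapping unified reads on the same strand merge
#' into read islands carrying the count of contributing reads; (4) islands
#' overlapping a probe by >= 1 nt are on-target; (5) on-target islands get an
#' empirical p-value against the off-target island count distribution, and
#' are called expressed at `p < p_cutoff`.
#'
#' @param reads stranded [interval_set] of uniquely mapped reads.
#' @param repeats optional [interval_set] of simple repeats.
#' @param probes optional [interval_set] of capture probes.
#' @param extension unified-read length in nt (default 150).
#' @param p_cutoff expression cutoff on the empirical p-value (default 0.1).
#' @return Data frame with one island per row: `chrom`, `start`, `end`,
#'   `strand`, `read_count`, `on_target`, `empirical_p`, `expressed`.
#' @export
call_islands <- function(reads, repeats = NULL, probes = NULL,
                         extension = 150, p_cutoff = 0.1) {
  if (any(!reads$strand %in% c("+", "-")))
    stop("reads must carry strand + or -")
  if (!is.null(repeats) && nrow(repeats) > 0L && nrow(reads) > 0L) {
    repeats <- merge_intervals(repeats)
    ovfrac <- numeric(nrow(reads))
    for (chr in unique(reads$chrom)) {
      ri <- which(reads$chrom == chr)
      pi_ <- which(repeats$chrom == chr)
      if (length(pi_) == 0L) next
      r <- IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri])
      p <- IRanges::IRanges(repeats$start[pi_] + 1L, repeats$end[pi_])
      ov <- IRanges::findOverlaps(r, p)
      if (length(ov) == 0L) next
      inter <- IRanges::pintersect(r[S4Vectors::queryHits(ov)],
                                   p[S4Vectors::subjectHits(ov)])
      wsum <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      ovfrac[ri[as.integer(names(wsum))]] <-
        as.numeric(wsum) / IRanges::width(r)[as.integer(names(wsum))]
    }
    reads <- reads[ovfrac < 0.5, , drop = FALSE]
  }
  if (nrow(reads) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      read_count = integer(0), on_target = logical(0),
                      empirical_p = numeric(0), expressed = logical(0)))
  ustart <- ifelse(reads$strand == "+", reads$start,
                   pmax(reads$end - extension, 0L))
  uend <- ifelse(reads$strand == "+", reads$start + extension, reads$end)
  islands <- list()
  for (chr in unique(reads$chrom)) for (str in c("+", "-")) {
    ri <- which(reads$chrom == chr & reads$strand == str)
    if (length(ri) == 0L) next
    u <- IRanges::IRanges(ustart[ri] + 1L, uend[ri])
    isl <- IRanges::reduce(u, min.gapwidth = 0L)   # overlap only, no abutment
    ov <- IRanges::findOverlaps(u, isl, select = "first")
    cnt <- tabulate(ov, nbins = length(isl))
    islands[[length(islands) + 1L]] <- data.frame(
      chrom = chr, start = IRanges::start(isl) - 1L, end = IRanges::end(isl),
      strand = str, read_count = cnt)
  }
  out <- do.call(rbind, islands)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$on_target <- FALSE
  if (!is.null(probes) && nrow(probes) > 0L) {
    for (chr in unique(out$chrom)) {
      ii <- which(out$chrom == chr)
      pi_ <- which(probes$chrom == chr)
      if (length(pi_) == 0L) next
      i <- IRanges::IRanges(out$start[ii] + 1L, out$end[ii])
      p <- IRanges::IRanges(probes$start[pi_] + 1L, probes$end[pi_])
      out$on_target[ii] <- IRanges::overlapsAny(i, p)
    }
  }
  out$empirical_p <- NA_real_
  off <- out$read_count[!out$on_target]
  if (any(out$on_target) && length(off) > 0L)
    out$empirical_p[out$on_target] <-
      empirical_pvalue(out$read_count[out$on_target], off)
  out$expressed <- !is.na(out$empirical_p) & out$empirical_p < p_cutoff
  out
}

#' Exosome-sensitivity stability call
#'
#' Sensitivity `s = max((E_exo - E_ctr) / E_exo, 0)` of a transcript's
#' expression to exosome depletion.  Transcripts with `s <= 0.25` are called
#' highly stable, `s >= 0.75` highly unstable, otherwise intermediate.
#'
#' @param E_exo expression after exosome depletion (> 0; vectors allowed).
#' @param E_ctr control expression.
#' @return Data frame with `s` and `klass` (`NA` where `E_exo <= 0`).
#' @export
exosome_sensitivity <- function(E_exo, E_ctr) {
  s <- ifelse(E_exo > 0, pmax((E_exo - E_ctr) / E_exo, 0), NA_real_)
  klass <- ifelse(is.na(s), NA_character_,
                  ifelse(s <= 0.25, "stable",
                         ifelse(s >= 0.75, "unstable", "intermediate")))
  data.frame(s = s, klass = klass)
}

#' Structure-probing log-fold change and pairing calls
#'
#' Per-position log2 fold change between denatured and native
#' reverse-transcription termination counts, depth-normalized and
#' regularized with a pseudo-count:
#' `lfc = log2(denatured' + kappa) - log2(native' + kappa)`.
#' Positions with `lfc > tau` are called paired (strict inequality).
#'
#' @param native,denatured equal-length count vectors.
#' @param depth_native,depth_denatured sequencing-depth factors (> 0); counts
#'   are divided by them.
#' @param kappa pseudo-count (default 5).
#' @param tau pairing cutoff on the lfc (default 1).
#' @return An object of class `probing_profile`: data frame with `lfc` and
#'   `paired_call`.
#' @export
probing_lfc <- function(native, denatured, depth_native = 1,
                        depth_denatured = 1, kappa = 5, tau = 1) {
  if (length(native) != length(denatured)) stop("length mismatch")
  if (depth_native <= 0 || depth_denatured <= 0) stop("depths must be > 0")
  lfc <- log2(denatured / depth_denatured + kappa) -
         log2(native / depth_native + kappa)
  out <- data.frame(lfc = lfc, paired_call = lfc > tau)
  class(out) <- c("probing_profile", "data.frame")
  out
}

#' Concordance of a predicted structure with probing calls
#'
#' Fraction of the structure's base-paired positions (both partners of every
#' pair, per-nucleotide counting) whose probing `paired_call` is `TRUE`.
#'
#' @param structure a [parse_structure()] result.
#' @param profile a `probing_profile` from [probing_lfc()] covering the
#'   structure's positions.
#' @return Fraction in `[0, 1]`.
#' @export
probing_concordance <- function(structure, profile) {
  pos <- sort(as.vector(structure$pairs))
  if (length(pos) == 0L) stop("structure has no paired positions")
  if (max(pos) > nrow(profile)) stop("profile shorter than structure")
  mean(profile$paired_call[pos])
}
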