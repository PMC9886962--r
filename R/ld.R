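#' Pairwise linkage disequilibrium (genotypic r-squared)
#'
#' For every same-chromosome locus pair within `max_dist_bp`, the squared
#' Pearson correlation of the dosage vectors over individuals non-missing
#' at both loci. This is the composite (genotypic) r2 -- phase-free, as
#' appropriate for unphased dosage data -- and is invariant to allele
#' relabeling (`g <-> 2 - g`). Pairs with fewer than `min_shared` shared
#' calls or zero variance at either locus are skipped.
#'
#' @param G a [genotype_matrix()] with loci sorted by position within
#'   chromosome.
#' @param max_dist_bp maximum pair distance (bp).
#' @param maf_min optional MAF filter applied before pairing.
#' @param min_shared minimum shared non-missing calls per pair.
#' @return data.frame of class `ld_pairs`: `chrom`, `pos1`, `pos2`,
#'   `dist`, `r2`.
#' @export
pairwise_r2 <- function(G, max_dist_bp = Inf, maf_min = 0, min_shared = 10) {
  if (maf_min > 0) {
    G <- maf_filter(G, threshold = maf_min)$genotypes
  }
  out <- list()
  for (chr in unique(G$loci$chrom)) {
    idx <- which(G$loci$chrom == chr)
    if (length(idx) < 2) next
    pos <- G$loci$pos[idx]
    if (is.unsorted(pos)) stop("loci must be sorted by position within chromosome")
    D <- G$dosages[, idx, drop = FALSE]
    shared <- crossprod(!is.na(D))
    suppressWarnings(r <- cor(D, use = "pairwise.complete.obs"))
    dist <- abs(outer(pos, pos, "-"))
    m <- length(idx)
    pair <- which(upper.tri(dist) & dist <= max_dist_bp & dist > 0 &
                    shared >= min_shared & !is.na(r), arr.ind = TRUE)
    if (nrow(pair) == 0) next
    out[[chr]] <- data.frame(
      chrom = chr,
      pos1 = pos[pair[, 1]], pos2 = pos[pair[, 2]],
      dist = dist[pair], r2 = r[pair]^2
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos1 = integer(0), pos2 = integer(0),
               dist = numeric(0), r2 = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Distance-binned LD decay curve
#'
#' @param pairs an `ld_pairs` data.frame from [pairwise_r2()].
#' @param bin_width_bp bin width; bins are `[0, w), [w, 2w), ...` up to
#'   the maximum observed distance, midpoints reported.
#' @return data.frame: `mid` (bin midpoint, bp), `mean_r2`, `n` (pairs in
#'   bin); empty bins are omitted.
#' @export
decay_curve <- function(pairs, bin_width_bp = 1000) {
  stopifnot(nrow(pairs) >= 1)
  bin <- floor(pairs$dist / bin_width_bp)
  agg <- tapply(pairs$r2, bin, mean)
  cnt <- tapply(pairs$r2, bin, length)
  data.frame(mid = (as.numeric(names(agg)) + 0.5) * bin_width_bp,
             mean_r2 = as.numeric(agg), n = as.numeric(cnt),
             row.names = NULL)
}

#' LD decay threshold-crossing distance
#'
#' Two summaries of "the distance at which LD drops below r2 = 0.2":
#' the headline `first_crossing` is the smallest bin midpoint at which
#' the (running-mean smoothed) decay curve first falls below the
#' threshold; `mean_distance_below` is the mean distance among pairs
#' with `r2 < threshold`. Both are reported since either reading of the
#' summary is defensible. If the curve never crosses, `first_crossing`
#' is `Inf` (a "> max distance" sentinel) with `crossed = FALSE`.
#'
#' @param pairs an `ld_pairs` data.frame.
#' @param r2_threshold threshold (default 0.2).
#' @param bin_width_bp bin width for the curve.
#' @param smooth_k running-mean window (odd; 1 = no smoothing).
#' @return list: `first_crossing` (bp or `Inf`), `mean_distance_below`,
#'   `crossed`, `curve` (the smoothed decay curve).
#' @export
threshold_distance <- function(pairs, r2_threshold = 0.2, bin_width_bp = 1000,
                               smooth_k = 3) {
  curve <- decay_curve(pairs, bin_width_bp)
  sm <- curve$mean_r2
  if (smooth_k > 1 && nrow(curve) >= smooth_k) {
    half <- (smooth_k - 1) / 2
    sm <- vapply(seq_along(sm), function(i) {
      lo <- max(1, i - half); hi <- min(length(sm), i + half)
      mean(curve$mean_r2[lo:hi])
    }, numeric(1))
  }
  curve$smoothed_r2 <- sm
  below <- which(sm < r2_threshold)
  crossed <- length(below) > 0
  list(
    first_crossing = if (crossed) curve$mid[below[1]] else Inf,
    mean_distance_below = if (any(pairs$r2 < r2_threshold))
      mean(pairs$dist[pairs$r2 < r2_threshold]) else NA_real_,
    crossed = crossed,
    curve = curve
  )
}
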