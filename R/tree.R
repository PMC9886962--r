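#' Population ALT-allele frequencies
#'
#' @param G a [genotype_matrix()].
#' @param by grouping column of `G$individuals` (default `"population"`).
#' @return populations x loci matrix of allele frequencies.
#' @export
pop_allele_freqs <- function(G, by = "population") {
  groups <- G$individuals[[by]]
  pops <- unique(groups)
  out <- t(vapply(pops, function(p) {
    colMeans(G$dosages[groups == p, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(n_loci(G))))
  rownames(out) <- pops
  out
}

#' Nei (1972) standard genetic distance between populations
#'
#' For biallelic loci with ALT frequencies `x`, `y` in two populations:
#' `Jx = mean(x^2 + (1-x)^2)`, `Jy` likewise, `Jxy = mean(x y +
#' (1-x)(1-y))`; the normalized identity is `I = Jxy / sqrt(Jx Jy)` and
#' `D = -ln I`. `I = 1` (identical profiles) gives `D = 0`; `I <= 0`
#' (complete non-identity) would give infinite distance and is capped at
#' `max_d` with a flag; numerical overshoot `I > 1` is clamped to 1.
#'
#' @param pop_freqs populations x loci matrix of ALT frequencies in
#'   `[0, 1]` (rownames = population labels).
#' @param max_d cap applied to infinite distances.
#' @return symmetric matrix of class `nei_dist` with zero diagonal;
#'   attribute `capped` is a logical matrix flagging capped entries.
#' @export
nei_distance <- function(pop_freqs, max_d = 10) {
  pop_freqs <- as.matrix(pop_freqs)
  if (ncol(pop_freqs) < 1) stop("need at least one locus")
  if (any(pop_freqs < 0 | pop_freqs > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  npop <- nrow(pop_freqs)
  labels <- rownames(pop_freqs)
  if (is.null(labels)) labels <- paste0("pop", seq_len(npop))
  D <- matrix(0, npop, npop, dimnames = list(labels, labels))
  capped <- matrix(FALSE, npop, npop, dimnames = list(labels, labels))
  J <- function(x, y) mean(x * y + (1 - x) * (1 - y))
  for (i in seq_len(npop - 1)) {
    for (j in (i + 1):npop) {
      x <- pop_freqs[i, ]; y <- pop_freqs[j, ]
      ok <- !is.na(x) & !is.na(y)
      I <- J(x[ok], y[ok]) / sqrt(J(x[ok], x[ok]) * J(y[ok], y[ok]))
      if (I > 1) I <- 1
      if (I <= 0) {
        D[i, j] <- D[j, i] <- max_d
        capped[i, j] <- capped[j, i] <- TRUE
      } else {
        D[i, j] <- D[j, i] <- min(-log(I), max_d)
        if (-log(I) > max_d) capped[i, j] <- capped[j, i] <- TRUE
      }
    }
  }
  structure(D, class = c("nei_dist", "matrix"), capped = capped)
}

#' UPGMA clustering of a distance matrix
#'
#' Classical agglomerative average-linkage: the closest pair of clusters
#' is merged at height `d/2`, and the distance from the merged cluster to
#' every other cluster is the size-weighted mean of the original pairwise
#' distances (arithmetic mean over all original leaf pairs). Ties are
#' broken by the lowest (row, column) index pair. The result is an
#' ultrametric rooted tree.
#'
#' @param D symmetric distance matrix with labelled rows (e.g. from
#'   [nei_distance()]), `n >= 2`.
#' @return an [ape::read.tree()] `phylo` object with branch lengths in
#'   distance units; leaf depths are equal (ultrametric).
#' @export
upgma <- function(D) {
  D <- unclass(as.matrix(D))
  if (anyNA(D)) stop("distance matrix contains NA/NaN")
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        dab <- D[active[a], active[b]]
        if (dab < bestd) {  # strict: first (lowest index pair) wins ties
          bestd <- dab; best <- c(a, b)
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    h <- bestd / 2
    newick_new <- sprintf("(%s:%.10g,%s:%.10g)",
                          newick[i], h - height[i], newick[j], h - height[j])
    # size-weighted average = mean over original leaf pairs
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <- (size[i] * D[i, k] + size[j] * D[j, k]) /
        (size[i] + size[j])
    }
    newick[i] <- newick_new
    height[i] <- h
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Bootstrap support for a UPGMA population tree
#'
#' Loci are resampled with replacement `n_boot` times; population allele
#' frequencies, Nei distances and the UPGMA tree are recomputed per
#' replicate, and each internal node of the original tree gets the
#' percentage of replicates containing the same clade.
#'
#' @param G a [genotype_matrix()] (>= 2 loci).
#' @param by grouping column of `G$individuals` (>= 2 groups).
#' @param n_boot number of replicates (0 = no supports).
#' @param seed RNG seed.
#' @param max_d distance cap passed to [nei_distance()].
#' @return the original UPGMA `phylo` tree; if `n_boot > 0`, node labels
#'   carry supports in `[0, 100]` and `tree$node.support` holds them
#'   numerically.
#' @export
bootstrap_support <- function(G, by = "population", n_boot = 1000, seed = 1,
                              max_d = 10) {
  freqs <- pop_allele_freqs(G, by = by)
  if (nrow(freqs) < 2) stop("need at least two groups")
  if (ncol(freqs) < 2) stop("need at least two loci")
  tree <- upgma(nei_distance(freqs, max_d = max_d))
  if (n_boot == 0) return(tree)
  set.seed(seed)
  L <- ncol(freqs)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- upgma(nei_distance(freqs[, idx, drop = FALSE], max_d = max_d))
  }
  counts <- ape::prop.clades(tree, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_boot
  tree$node.label <- formatC(support, format = "fg")
  tree$node.support <- support
  tree
}
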