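#' Per-locus minor allele frequency
#'
#' ALT-allele frequency `f` is the mean dosage over non-missing calls
#' divided by 2; MAF is `min(f, 1 - f)`. Loci with no observed calls get
#' `NA`.
#'
#' @param G a [genotype_matrix()].
#' @return numeric vector of MAF values in `[0, 0.5]` (or `NA`).
#' @export
locus_maf <- function(G) {
  f <- colMeans(G$dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA
  pmin(f, 1 - f)
}

qc_report <- function(n_in, n_kept, n_removed_maf = 0, n_removed_missing = 0,
                      maf = NULL, extra = list()) {
  stopifnot(n_in == n_kept + n_removed_maf + n_removed_missing)
  structure(c(list(n_in = n_in, n_kept = n_kept,
                   n_removed_maf = n_removed_maf,
                   n_removed_missing = n_removed_missing, maf = maf), extra),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d in, %d kept (%d removed by MAF, %d by missingness)\n",
              x$n_in, x$n_kept, x$n_removed_maf, x$n_removed_missing))
  invisible(x)
}

#' Remove loci below a minor-allele-frequency threshold
#'
#' Loci with `MAF < threshold` (strict) are removed; locus order is
#' preserved. Loci with all calls missing are removed too but counted
#' under missingness, not MAF. Idempotent: a second application at the
#' same threshold removes nothing.
#'
#' @param G a [genotype_matrix()].
#' @param threshold MAF cutoff in `[0, 0.5]`; the conventional genome-scan
#'   default is 0.05.
#' @return list with components `genotypes` (filtered) and `report`
#'   (`qc_report`).
#' @export
maf_filter <- function(G, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5) stop("threshold must lie in [0, 0.5]")
  maf <- locus_maf(G)
  all_missing <- is.na(maf)
  low <- !all_missing & maf < threshold
  keep <- !all_missing & !low
  list(
    genotypes = G[, keep],
    report = qc_report(n_loci(G), sum(keep), n_removed_maf = sum(low),
                       n_removed_missing = sum(all_missing), maf = maf)
  )
}

#' Remove loci then individuals with excessive missingness
#'
#' Loci whose missing-call rate exceeds `max_locus_missing` are removed
#' first; then individuals whose missing rate (over the remaining loci)
#' exceeds `max_indiv_missing`.
#'
#' @param G a [genotype_matrix()].
#' @param max_locus_missing,max_indiv_missing allowed missing fractions in
#'   `[0, 1]` (strictly greater rates are removed).
#' @return list with `genotypes` and `report`; the report's `extra` fields
#'   give `n_indiv_in`/`n_indiv_kept`.
#' @export
missingness_filter <- function(G, max_locus_missing = 0.5,
                               max_indiv_missing = 0.5) {
  stopifnot(max_locus_missing >= 0, max_locus_missing <= 1,
            max_indiv_missing >= 0, max_indiv_missing <= 1)
  locus_rate <- colMeans(is.na(G$dosages))
  keep_loci <- locus_rate <= max_locus_missing
  G2 <- G[, keep_loci]
  indiv_rate <- rowMeans(is.na(G2$dosages))
  keep_ind <- indiv_rate <= max_indiv_missing
  G3 <- G2[keep_ind, ]
  list(
    genotypes = G3,
    report = qc_report(n_loci(G), sum(keep_loci),
                       n_removed_missing = sum(!keep_loci),
                       extra = list(n_indiv_in = n_ind(G),
                                    n_indiv_kept = sum(keep_ind)))
  )
}

#' Mean-dosage imputation of missing calls
#'
#' Each missing cell is replaced by its locus mean dosage over observed
#' calls; observed cells are untouched, so column means are conserved.
#' The result is continuous-valued (marked `imputed`), which is what the
#' centered-dosage statistics downstream (RDA, LD, DAPC) expect; the mean
#' is the single value that minimizes the added variance. Stages that
#' need integer dosages (the admixture EM) instead skip missing cells via
#' the observed-data likelihood and should be given the unimputed matrix.
#'
#' @param G a [genotype_matrix()] with no all-missing loci (run
#'   [maf_filter()] or [missingness_filter()] first).
#' @return an imputed [genotype_matrix()] with no missing cells.
#' @export
impute_mean_dosage <- function(G) {
  d <- G$dosages
  if (!anyNA(d)) return(genotype_matrix(d, G$loci, G$individuals, imputed = TRUE))
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu))) {
    stop("all-missing locus present; filter loci before imputation")
  }
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  genotype_matrix(d, G$loci, G$individuals, imputed = TRUE)
}
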