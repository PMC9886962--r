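#' Construct a genotype matrix object
#'
#' The central container of the package: an individuals x loci matrix of
#' ALT-allele dosages (0, 1, 2; `NA` marks a missing call) together with
#' locus metadata (chromosome, 1-based position, REF/ALT alleles) and
#' individual metadata (id, population, site). Dosages count the ALT
#' allele as written in the source file; which allele is minor is always
#' recomputed from the data (see [locus_maf()]).
#'
#' After mean-dosage imputation ([impute_mean_dosage()]) the dosage matrix
#' becomes continuous; the `imputed` attribute records this and integer
#' validation is relaxed.
#'
#' @param dosages numeric matrix, individuals in rows, loci in columns.
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt` (one row
#'   per locus). `pos` is 1-based. Optional column `id`.
#' @param individuals data.frame with columns `id`, `population`, `site`
#'   (one row per individual). `id` must be unique.
#' @param imputed logical; `TRUE` for continuous (imputed) dosages.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, loci, individuals, imputed = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(loci$id)) {
    loci$id <- paste0(loci$chrom, ":", loci$pos)
  }
  stopifnot(
    nrow(dosages) == nrow(individuals),
    ncol(dosages) == nrow(loci),
    all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
    all(c("id", "population", "site") %in% names(individuals))
  )
  if (anyDuplicated(individuals$id)) {
    stop("individual ids must be unique")
  }
  vals <- dosages[!is.na(dosages)]
  if (!imputed && length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA (use imputed = TRUE for continuous values)")
  }
  if (imputed && length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    stop("imputed dosages must lie in [0, 2]")
  }
  rownames(dosages) <- individuals$id
  colnames(dosages) <- loci$id
  structure(
    list(dosages = dosages, loci = as.data.frame(loci),
         individuals = as.data.frame(individuals)),
    class = "genotype_matrix", imputed = imputed
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci (%s; %.2f%% missing)\n",
    n_ind(x), n_loci(x),
    if (isTRUE(attr(x, "imputed"))) "imputed/continuous" else "discrete dosages",
    100 * mean(is.na(x$dosages))
  ))
  pops <- unique(x$individuals$population)
  cat(sprintf("populations: %s\n", paste(head(pops, 8), collapse = ", ")))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param G a `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(G) nrow(G$dosages)

#' @rdname n_ind
#' @export
n_loci <- function(G) ncol(G$dosages)

#' Subset a genotype matrix by individuals and/or loci
#' @param x a `genotype_matrix`.
#' @param i individual index (row) selector.
#' @param j locus index (column) selector.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  genotype_matrix(
    x$dosages[i, j, drop = FALSE],
    x$loci[j, , drop = FALSE],
    x$individuals[i, , drop = FALSE],
    imputed = isTRUE(attr(x, "imputed"))
  )
}

# site-level vector expanded to one value per individual, in individual order
broadcast_to_individuals <- function(values, sites, G) {
  idx <- match(G$individuals$site, sites)
  if (anyNA(idx)) {
    stop("sites missing from environment table: ",
         paste(unique(G$individuals$site[is.na(idx)]), collapse = ", "))
  }
  values[idx]
}
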