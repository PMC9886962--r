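#' Read a VCF file into a genotype matrix
#'
#' Diploid GT calls are converted to ALT-allele dosages: `0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> `NA`. Phased separators
#' (`|`) are accepted. Multi-allelic records are an error in strict mode
#' (default) or dropped with a warning.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @param individuals optional data.frame with columns `id`, `population`,
#'   `site` attaching sample metadata; matched by id. Samples absent from
#'   it get `NA` metadata.
#' @param multiallelic `"error"` (strict) or `"drop"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, individuals = NULL,
                     multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!"GT" %in% unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))) {
    stop("VCF has no GT field in FORMAT")
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop("multi-allelic record(s), e.g. ", fix$CHROM[multi][1], ":",
           fix$POS[multi][1], "; use multiallelic = \"drop\" to skip them")
    }
    warning(sum(multi), " multi-allelic record(s) dropped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    bad <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop("unsupported GT value(s): ",
                       paste(unique(g[bad]), collapse = ", "))
    out
  }
  dos <- apply(gt, 2, code)
  dos <- matrix(dos, nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste0(fix$CHROM, ":", fix$POS), fix$ID))
  ids <- colnames(gt)
  ind <- data.frame(id = ids, population = NA_character_, site = NA_character_)
  if (!is.null(individuals)) {
    m <- match(ids, individuals$id)
    ind$population <- individuals$population[m]
    ind$site <- individuals$site[m]
  }
  genotype_matrix(t(dos), loci, ind)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param G a [genotype_matrix()] with discrete dosages.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  if (isTRUE(attr(G, "imputed"))) {
    stop("cannot write continuous (imputed) dosages as VCF genotypes")
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(G$dosages)  # loci x individuals
  gt <- matrix(gt_code[as.character(dos)], nrow = nrow(dos))
  gt[is.na(dos)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grazescan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$individuals$id), collapse = "\t")
  )
  body <- paste(G$loci$chrom, G$loci$pos, G$loci$id, G$loci$ref, G$loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a dosage TSV
#'
#' Layout: one row per individual; columns `id`, `population`, `site`,
#' then one column per locus named `chrom:pos:ref:alt`. Values must be 0,
#' 1, 2 or `NA`.
#'
#' @param path TSV file.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("id", "population", "site"), names(d))
  if (!"id" %in% meta_cols) stop("dosage TSV must have an 'id' column")
  if (anyDuplicated(d$id)) {
    stop("duplicated individual id at line ",
         which(duplicated(d$id))[1] + 1L, ": ", d$id[duplicated(d$id)][1])
  }
  locus_cols <- setdiff(names(d), meta_cols)
  dos <- as.matrix(d[, locus_cols, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- which(is.na(suppressWarnings(apply(dos, 2, as.numeric))) &
                   !is.na(dos), arr.ind = TRUE)
    stop("non-numeric dosage at line ", bad[1, 1] + 1L,
         ", locus ", locus_cols[bad[1, 2]])
  }
  bad <- which(!is.na(dos) & !dos %in% c(0, 1, 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid dosage value ", dos[bad[1, , drop = FALSE]],
         " at line ", bad[1, 1] + 1L, ", locus ", locus_cols[bad[1, 2]],
         " (allowed: 0, 1, 2, NA)")
  }
  parts <- strsplit(locus_cols, ":", fixed = TRUE)
  ok <- lengths(parts) == 4
  loci <- data.frame(
    chrom = vapply(parts, function(p) p[1], character(1)),
    pos = suppressWarnings(as.integer(vapply(parts, function(p) p[2], character(1)))),
    ref = vapply(parts, function(p) if (length(p) >= 3) p[3] else "N", character(1)),
    alt = vapply(parts, function(p) if (length(p) >= 4) p[4] else "N", character(1)),
    id = locus_cols
  )
  if (anyNA(loci$pos)) {
    loci$pos[is.na(loci$pos)] <- seq_len(sum(is.na(loci$pos)))
    if (!all(ok)) loci$chrom[!ok] <- "un"
  }
  ind <- data.frame(id = d$id,
                    population = if ("population" %in% meta_cols) d$population else NA_character_,
                    site = if ("site" %in% meta_cols) d$site else NA_character_)
  genotype_matrix(dos, loci, ind)
}

#' @rdname read_dosage_tsv
#' @param G a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, path) {
  loc_id <- paste(G$loci$chrom, G$loci$pos, G$loci$ref, G$loci$alt, sep = ":")
  out <- cbind(G$individuals[, c("id", "population", "site")],
               as.data.frame(G$dosages))
  names(out)[-(1:3)] <- loc_id
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-level environmental predictor table
#'
#' Tab-delimited with a header; the first column (or a column named
#' `site`) holds site labels, remaining numeric columns are predictors.
#' Non-numeric columns (e.g. a soil-zone label) are kept as metadata in
#' the `metadata` attribute. Sites with any missing predictor value are
#' dropped with a warning, mirroring the practice of excluding sites
#' without soil-test information from a GEA.
#'
#' @param path TSV file.
#' @return data.frame of class `env_table`: column `site` then numeric
#'   predictors; attribute `metadata` holds any non-numeric columns.
#' @export
read_env_table <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site" %in% names(d)) names(d)[1] <- "site"
  if (anyDuplicated(d$site)) stop("duplicated site label: ",
                                  d$site[duplicated(d$site)][1])
  is_num <- vapply(d, is.numeric, logical(1))
  is_num["site"] <- FALSE
  meta <- d[, !is_num & names(d) != "site", drop = FALSE]
  pred <- d[, is_num, drop = FALSE]
  incomplete <- rowSums(is.na(pred)) > 0
  if (any(incomplete)) {
    warning("dropping ", sum(incomplete), " site(s) with missing predictor ",
            "values: ", paste(d$site[incomplete], collapse = ", "))
  }
  out <- cbind(data.frame(site = d$site), pred)[!incomplete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metadata") <- meta[!incomplete, , drop = FALSE]
  class(out) <- c("env_table", "data.frame")
  out
}

#' Coerce a data.frame to an environment table
#' @param d data.frame with a `site` column and numeric predictor columns.
#' @return an `env_table`.
#' @export
as_env_table <- function(d) {
  if (inherits(d, "env_table")) return(d)
  stopifnot("site" %in% names(d))
  is_num <- vapply(d, is.numeric, logical(1))
  out <- cbind(data.frame(site = d$site), d[, is_num, drop = FALSE])
  attr(out, "metadata") <- d[, !is_num & names(d) != "site", drop = FALSE]
  class(out) <- c("env_table", "data.frame")
  out
}

env_predictors <- function(E) setdiff(names(E), "site")

#' Read gene annotation intervals (GFF3 or BED)
#'
#' Coordinates are normalized to the package-wide 1-based inclusive
#' convention; BED's half-open 0-based intervals are converted at this
#' boundary. For GFF3, `gene`-type features are used when present
#' (otherwise all features); the gene id is taken from the `ID` or `Name`
#' attribute and the free-text annotation from `description`, `product`
#' or `Note`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return data.frame of class `gene_annotation` with columns `chrom`,
#'   `start`, `end`, `gene_id`, `annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  d <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(d) && any(d$type == "gene")) {
    d <- d[d$type == "gene", , drop = FALSE]
  }
  gene_id <- rep(NA_character_, nrow(d))
  for (col in c("ID", "Name", "name", "gene_id")) {
    if (col %in% names(d)) {
      gene_id <- ifelse(is.na(gene_id), as.character(d[[col]]), gene_id)
    }
  }
  if (anyNA(gene_id)) {
    gene_id[is.na(gene_id)] <- paste0("feature", which(is.na(gene_id)))
  }
  ann <- rep(NA_character_, nrow(d))
  for (col in c("description", "product", "Note", "note")) {
    if (col %in% names(d)) {
      val <- vapply(d[[col]], function(x) {
        x <- unlist(x)
        if (length(x) == 0 || all(is.na(x))) NA_character_ else paste(x, collapse = "; ")
      }, character(1))
      ann <- ifelse(is.na(ann), val, ann)
    }
  }
  out <- data.frame(chrom = as.character(d$seqnames), start = d$start,
                    end = d$end, gene_id = gene_id, annotation = ann,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("annotation interval with start > end")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read a per-genotype phenotype table
#'
#' Tab-delimited with a header; first column (or a column named `id`)
#' identifies the genotype, remaining numeric columns are traits. Trait
#' values must be finite where present.
#'
#' @param path TSV file.
#' @return data.frame: column `id` then numeric traits.
#' @export
read_phenotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) names(d)[1] <- "id"
  if (anyDuplicated(d$id)) stop("duplicated genotype id: ",
                                d$id[duplicated(d$id)][1])
  traits <- setdiff(names(d), "id")
  for (tr in traits) {
    if (!is.numeric(d[[tr]])) stop("trait column '", tr, "' is not numeric")
    if (any(is.infinite(d[[tr]]))) stop("non-finite value in trait '", tr, "'")
  }
  d
}
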