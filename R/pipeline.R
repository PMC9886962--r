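#' Build a pipeline configuration
#'
#' Either programmatically (a named list of overrides) or from a YAML
#' file. The configuration holds input paths (or a `simulate` block to
#' generate inputs), per-stage toggles and parameters, and one global
#' seed from which every stochastic stage derives its own sub-seed by
#' stable hashing of the stage name -- so toggling one stage never
#' shifts another stage's randomness.
#'
#' @param ... named overrides of the defaults (see
#'   `pipeline_defaults()`), or a single list.
#' @param file optional YAML file of overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  if (!is.null(file)) {
    over <- utils::modifyList(yaml::read_yaml(file), over)
  }
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    inputs = list(genotypes = NULL, env = NULL, annotation = NULL,
                  phenotypes = NULL),
    simulate = NULL,  # list of sim_config() overrides, or NULL
    stages = list(qc = TRUE, structure = TRUE, dapc = TRUE, tree = TRUE,
                  gea = TRUE, ld = TRUE, pheno = TRUE, regress = TRUE),
    qc = list(maf = 0.05, max_locus_missing = 0.5, max_indiv_missing = 0.5),
    structure = list(kmin = 1, kmax = 5, runs = 5, n_init = 2,
                     focal_ancestry = NULL),
    dapc = list(max_k = 6),
    tree = list(boot = 100),
    gea = list(axes = "broken_stick", robust = "mcd", qmethod = "storey",
               qmax = 0.01),
    ld = list(max_dist = 1e6, bin = 1000, maf = 0.05, r2_threshold = 0.2),
    pheno = list(alpha = 0.05, group = "population")
  )
}

# deterministic sub-seed per stage from the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in the canonical order -- QC/imputation,
#' admixture structure scan, DAPC, Nei/UPGMA tree, RDA genome scan, LD
#' decay, phenotype ANOVA and membership regression -- writing each
#' stage's outputs (TSV / Newick / JSON) plus a manifest (input hashes,
#' parameters, seed, package version) under `out_dir`. Rerunning with an
#' identical config and seed reproduces byte-identical outputs. A stage
#' failure halts the run, naming the stage; earlier outputs are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- inputs
  if (!is.null(config$simulate)) {
    sim_args <- utils::modifyList(config$simulate,
                                  list(seed = stage_seed(config$seed, "simulate")))
    dataset <- in_stage("simulate", do.call(sim_config, sim_args))
    dataset <- in_stage("simulate", simulate_dataset(dataset))
    in_stage("simulate", write_dataset(dataset, file.path(out_dir, "inputs")))
    G <- dataset$genotypes
    env <- as_env_table(dataset$env)
    pheno <- dataset$phenotypes
    annotation <- NULL
    results$truth <- dataset$truth
  } else {
    paths <- config$inputs
    if (is.null(paths$genotypes)) stop("no genotype input and no simulate block")
    G <- in_stage("inputs", if (grepl("\\.vcf(\\.gz)?$", paths$genotypes))
      read_vcf(paths$genotypes) else read_dosage_tsv(paths$genotypes))
    env <- if (!is.null(paths$env)) in_stage("inputs", read_env_table(paths$env)) else NULL
    pheno <- if (!is.null(paths$phenotypes))
      in_stage("inputs", read_phenotypes(paths$phenotypes)) else NULL
    annotation <- if (!is.null(paths$annotation))
      in_stage("inputs", read_annotation(paths$annotation)) else NULL
  }

  ## ---- qc
  if (isTRUE(config$stages$qc)) {
    qc1 <- in_stage("qc", missingness_filter(G, config$qc$max_locus_missing,
                                             config$qc$max_indiv_missing))
    qc2 <- in_stage("qc", maf_filter(qc1$genotypes, config$qc$maf))
    G <- qc2$genotypes
    rep_json <- list(
      missingness = qc1$report[c("n_in", "n_kept", "n_removed_missing")],
      maf = qc2$report[c("n_in", "n_kept", "n_removed_maf")]
    )
    jsonlite::write_json(rep_json, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    results$qc <- list(missingness = qc1$report, maf = qc2$report)
  }
  G_imp <- in_stage("qc", impute_mean_dosage(G))

  ## ---- structure
  Qcons <- NULL
  if (isTRUE(config$stages$structure)) {
    st <- config$structure
    scan <- in_stage("structure", admixture_scan(
      G, kmin = st$kmin, kmax = st$kmax, runs = st$runs,
      seed = stage_seed(config$seed, "structure"), n_init = st$n_init))
    wt(scan$evanno, "evanno.tsv")
    if (!is.null(scan$Q_consensus)) {
      Qcons <- scan$Q_consensus
      qdf <- cbind(data.frame(id = rownames(Qcons)), as.data.frame(Qcons))
      wt(qdf, "q_matrix.tsv")
    }
    results$structure <- scan
  }

  ## ---- dapc
  if (isTRUE(config$stages$dapc)) {
    dp <- in_stage("dapc", dapc(G_imp, max_k = config$dapc$max_k,
                                seed = stage_seed(config$seed, "dapc")))
    wt(cbind(data.frame(id = names(dp$assignments),
                        cluster = dp$assignments),
             as.data.frame(dp$scores)), "dapc_assignments.tsv")
    wt(dp$bic, "dapc_bic.tsv")
    results$dapc <- dp
  }

  ## ---- tree
  if (isTRUE(config$stages$tree)) {
    tree <- in_stage("tree", bootstrap_support(
      G, n_boot = config$tree$boot, seed = stage_seed(config$seed, "tree")))
    ape::write.tree(tree, file.path(out_dir, "upgma.nwk"))
    D <- nei_distance(pop_allele_freqs(G))
    wt(cbind(data.frame(population = rownames(D)),
             as.data.frame(unclass(D))), "nei_distance.tsv")
    results$tree <- tree
  }

  ## ---- gea
  if (isTRUE(config$stages$gea)) {
    if (is.null(env)) stop("pipeline stage 'gea' failed: no environment table")
    scan <- in_stage("gea", rda_scan(
      G_imp, env, axes = config$gea$axes, robust = config$gea$robust,
      qmethod = config$gea$qmethod, q_max = config$gea$qmax,
      seed = stage_seed(config$seed, "gea")))
    wt(scan$table, "gea_scan.tsv")
    outl <- scan$table[scan$table$outlier, , drop = FALSE]
    if (!is.null(annotation) && nrow(outl)) {
      outl <- in_stage("gea", map_candidates(outl, annotation))
    }
    wt(outl, "gea_candidates.tsv")
    jsonlite::write_json(list(lambda = scan$lambda, K = scan$K,
                              n_outliers = sum(scan$table$outlier)),
                         file.path(out_dir, "gea_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$gea <- scan
  }

  ## ---- ld
  if (isTRUE(config$stages$ld)) {
    pairs <- in_stage("ld", pairwise_r2(G_imp, max_dist_bp = config$ld$max_dist,
                                        maf_min = config$ld$maf))
    td <- in_stage("ld", threshold_distance(
      pairs, r2_threshold = config$ld$r2_threshold,
      bin_width_bp = config$ld$bin))
    wt(td$curve, "ld_decay_curve.tsv")
    jsonlite::write_json(
      list(first_crossing_bp = if (is.finite(td$first_crossing))
             td$first_crossing else "gt_max_distance",
           mean_distance_below_bp = td$mean_distance_below,
           r2_threshold = config$ld$r2_threshold, n_pairs = nrow(pairs)),
      file.path(out_dir, "ld_summary.json"), auto_unbox = TRUE, digits = NA)
    results$ld <- td
  }

  ## ---- pheno
  if (isTRUE(config$stages$pheno) && !is.null(pheno)) {
    grp <- G$individuals[[config$pheno$group]][match(pheno$id, G$individuals$id)]
    ok <- !is.na(grp)
    tuk <- list()
    for (tr in setdiff(names(pheno), "id")) {
      tuk[[tr]] <- in_stage("pheno", anova_tukey(pheno[[tr]][ok], grp[ok],
                                                 alpha = config$pheno$alpha))
    }
    tt <- do.call(rbind, lapply(names(tuk), function(tr) {
      cbind(data.frame(trait = tr), tuk[[tr]]$table,
            data.frame(sem = tuk[[tr]]$sem, p_value = tuk[[tr]]$p_value))
    }))
    wt(tt, "pheno_tukey.tsv")
    results$pheno <- tuk
  }

  ## ---- regress
  if (isTRUE(config$stages$regress) && !is.null(pheno) && !is.null(Qcons)) {
    focal <- config$structure$focal_ancestry
    if (is.null(focal)) focal <- colnames(Qcons)[1]
    memb <- Qcons[match(pheno$id, rownames(Qcons)), focal]
    reg <- do.call(rbind, lapply(setdiff(names(pheno), "id"), function(tr) {
      r <- in_stage("regress", membership_regression(pheno[[tr]], memb))
      data.frame(trait = tr, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, p_value = r$p_value, n = r$n)
    }))
    wt(reg, "membership_regression.tsv")
    results$regress <- reg
  }

  ## ---- manifest
  input_files <- list.files(file.path(out_dir, "inputs"), full.names = TRUE)
  if (!is.null(config$inputs)) {
    input_files <- c(input_files,
                     unlist(config$inputs[!vapply(config$inputs, is.null,
                                                  logical(1))]))
  }
  hashes <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  } else list()
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("grazescan")),
    seed = config$seed,
    parameters = unclass(config),
    input_md5 = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
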