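#' Simulation configuration for the synthetic landscape-genomics dataset
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' sampling design the package targets: a modest number of perennial forage
#' populations (one per ranch site), each a sample of clonally propagated
#' genotypes, drawn from two ancestral gene pools (e.g. the sativa and
#' falcata backgrounds of cultivated alfalfa) with a per-population
#' admixture gradient, sites grouped into soil zones that structure the
#' environmental covariates, a minority of loci whose site-level allele
#' frequency tracks one environmental predictor, block-wise linkage
#' disequilibrium along chromosomes, and phenotypes that respond linearly
#' to ancestry.
#'
#' @param n_pops number of populations (= sites).
#' @param n_per_pop genotypes sampled per population.
#' @param n_loci total number of SNP loci.
#' @param n_chrom number of chromosomes loci are spread over.
#' @param chrom_length_bp chromosome length in bp.
#' @param fst divergence of the two ancestral pools, in `[0, 1)`
#'   (Balding-Nichols style).
#' @param admixture_alpha concentration of the per-individual Beta draw
#'   around the population's mean ancestry; larger = tighter.
#' @param n_adaptive number of planted environment-coupled loci.
#' @param adaptive_slope log-odds change in site allele frequency per SD of
#'   the coupled predictor.
#' @param block_len_bp mean haplotype-block length (bp) of the LD generator.
#' @param missing_rate fraction of dosage calls masked at random.
#' @param env_spec data.frame describing predictors: columns `predictor`,
#'   `mean`, `sd`, `zone_sd` (SD of soil-zone offsets). Default: the six
#'   predictors used by the GEA stage (soil K, P, S, pH and summer/winter
#'   extreme temperatures) at field-plausible scales.
#' @param n_zones number of soil zones sites are grouped into.
#' @param pheno_spec data.frame describing traits: columns `trait`,
#'   `intercept`, `slope` (per unit sativa ancestry), `noise_sd`.
#' @param seed RNG seed; identical seed gives bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 14, n_per_pop = 10, n_loci = 2000,
                       n_chrom = 4, chrom_length_bp = 2e6,
                       fst = 0.3, admixture_alpha = 10,
                       n_adaptive = 20, adaptive_slope = 1.5,
                       block_len_bp = 5000, missing_rate = 0,
                       env_spec = default_env_spec(),
                       n_zones = 4,
                       pheno_spec = default_pheno_spec(),
                       seed = 1) {
  cfg <- list(
    n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
    n_chrom = n_chrom, chrom_length_bp = chrom_length_bp, fst = fst,
    admixture_alpha = admixture_alpha, n_adaptive = n_adaptive,
    adaptive_slope = adaptive_slope, block_len_bp = block_len_bp,
    missing_rate = missing_rate, env_spec = env_spec, n_zones = n_zones,
    pheno_spec = pheno_spec, seed = seed
  )
  counts <- c("n_pops", "n_per_pop", "n_loci", "n_chrom", "chrom_length_bp",
              "block_len_bp")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop(nm, " must be a positive count")
    }
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (n_adaptive < 0 || n_adaptive > n_loci) {
    stop("n_adaptive must lie in [0, n_loci]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  stopifnot(all(c("predictor", "mean", "sd", "zone_sd") %in% names(env_spec)),
            all(c("trait", "intercept", "slope", "noise_sd") %in% names(pheno_spec)))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_env_spec <- function() {
  data.frame(
    predictor = c("soil_K", "soil_P", "soil_S", "soil_pH",
                  "temp_summer_extreme", "temp_winter_extreme"),
    mean = c(400, 25, 12, 7.5, 34, -38),
    sd = c(120, 8, 5, 0.4, 2, 3),
    zone_sd = c(80, 5, 3, 0.3, 1.5, 2.5)
  )
}

#' @rdname sim_config
#' @export
default_pheno_spec <- function() {
  data.frame(
    trait = c("fall_height_cm", "days_to_flower_gdd", "cp_pct_dm"),
    intercept = c(18, 950, 18.5),
    slope = c(22, -140, -1.8),
    noise_sd = c(7, 55, 0.8)
  )
}

#' Draw allele frequencies for two diverged ancestral gene pools
#'
#' Balding-Nichols model: each locus has a common ancestral frequency and
#' the two pools draw their frequency from a Beta distribution around it
#' whose spread is governed by `fst`. `fst = 0` returns two identical
#' vectors (zero divergence).
#'
#' @param n_loci number of loci.
#' @param fst pool divergence in `[0, 1)`.
#' @param seed RNG seed.
#' @param base_freq optional length-`n_loci` vector of ancestral
#'   frequencies in (0, 1); drawn Uniform(0.1, 0.9) when `NULL`.
#' @return list with components `freq_a`, `freq_b` (numeric vectors in
#'   (0, 1)) and `base_freq`.
#' @export
simulate_ancestral_freqs <- function(n_loci, fst, seed = 1, base_freq = NULL) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (n_loci < 1) stop("n_loci must be >= 1")
  set.seed(seed)
  if (is.null(base_freq)) {
    base_freq <- runif(n_loci, 0.1, 0.9)
  }
  stopifnot(length(base_freq) == n_loci, all(base_freq > 0 & base_freq < 1))
  if (fst == 0) {
    return(list(freq_a = base_freq, freq_b = base_freq, base_freq = base_freq))
  }
  conc <- (1 - fst) / fst
  draw <- function() {
    p <- rbeta(n_loci, base_freq * conc, (1 - base_freq) * conc)
    pmin(pmax(p, 1e-3), 1 - 1e-3)
  }
  list(freq_a = draw(), freq_b = draw(), base_freq = base_freq)
}

#' Simulate a full synthetic landscape-genomics dataset
#'
#' Generates genotypes, site environments, phenotypes and a ground-truth
#' record under the model described in [sim_config()]. Neutral loci get
#' individual ALT-allele frequency `q_i * pA + (1 - q_i) * pB` where `q_i`
#' is the individual's sativa admixture proportion; planted adaptive loci
#' instead get a site-level frequency `plogis(qlogis(p0) + slope * z_site)`
#' with `z_site` the standardized coupled predictor. Dosages are sums of
#' two haplotypes; within each haplotype, alleles are generated from a
#' single latent uniform per LD block (block boundaries are re-drawn per
#' haplotype at exponential spacings with mean `block_len_bp`), so loci in
#' the same block are strongly correlated while marginal frequencies stay
#' exact. Ancestral frequencies are spatially autocorrelated along the
#' chromosome on the same length scale, which keeps within-block r2 high,
#' as in real haplotype data.
#'
#' @param config a [sim_config()].
#' @return list with components `genotypes` ([genotype_matrix()]), `env`
#'   (site x predictor data.frame, first columns `site`, `zone`),
#'   `phenotypes` (data.frame keyed by `id`), `truth` (list: `true_Q`,
#'   `adaptive_loci`, `block_len_bp`, `pheno_slopes`, `freq_a`, `freq_b`,
#'   `pop_mean_ancestry`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pops * config$n_per_pop
  L <- config$n_loci

  ## --- locus map: positions sorted within chromosome
  per_chrom <- diff(floor(seq(0, L, length.out = config$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m) {
    sort(sample.int(config$chrom_length_bp, m, replace = FALSE))
  }), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  loci <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     id = paste0(chrom, ":", pos))

  ## --- ancestral frequencies, autocorrelated along each chromosome on
  ## the LD-block length scale: the common ancestral frequency and each
  ## pool's Balding-Nichols deviate are driven by AR1 Gaussian scores, so
  ## loci within a block have similar frequencies in both pools (as in
  ## real haplotype data) while marginals stay Balding-Nichols
  ar1_scores <- function(scale_bp) {
    z <- numeric(L)
    start <- 1
    for (m in per_chrom) {
      idx <- start:(start + m - 1)
      zc <- numeric(m)
      zc[1] <- rnorm(1)
      if (m > 1) {
        rho <- exp(-diff(pos[idx]) / scale_bp)
        eps <- rnorm(m - 1)
        for (j in 2:m) {
          zc[j] <- rho[j - 1] * zc[j - 1] + sqrt(1 - rho[j - 1]^2) * eps[j - 1]
        }
      }
      z[idx] <- zc
      start <- start + m
    }
    z
  }
  ## frequency-similarity scale > block length: within-block pairs then
  ## have nearly matched frequencies and their r2 is governed by block
  ## survival rather than by the frequency-mismatch cap
  freq_scale <- 2.5 * config$block_len_bp
  base_freq <- pmin(pmax(plogis(1.2 * ar1_scores(freq_scale)), 0.1), 0.9)
  if (config$fst == 0) {
    anc <- list(freq_a = base_freq, freq_b = base_freq, base_freq = base_freq)
  } else {
    conc <- (1 - config$fst) / config$fst
    pool_freq <- function() {
      p <- qbeta(pnorm(ar1_scores(freq_scale)), base_freq * conc, (1 - base_freq) * conc)
      pmin(pmax(p, 1e-3), 1 - 1e-3)
    }
    anc <- list(freq_a = pool_freq(), freq_b = pool_freq(),
                base_freq = base_freq)
  }

  ## --- individuals: admixture gradient across populations
  pop_names <- sprintf("pop%02d", seq_len(config$n_pops))
  pop_mean <- seq(0.08, 0.92, length.out = config$n_pops)
  population <- rep(pop_names, each = config$n_per_pop)
  a <- config$admixture_alpha
  q_sativa <- rbeta(n, rep(pop_mean, each = config$n_per_pop) * a,
                    (1 - rep(pop_mean, each = config$n_per_pop)) * a)
  q_sativa <- pmin(pmax(q_sativa, 1e-4), 1 - 1e-4)
  individuals <- data.frame(
    id = sprintf("%s_g%02d", population, rep(seq_len(config$n_per_pop), config$n_pops)),
    population = population, site = population
  )

  ## --- environment: zone offsets + site noise, constant within site
  zones <- paste0("zone", rep_len(seq_len(config$n_zones), config$n_pops))
  env <- data.frame(site = pop_names, zone = zones)
  for (r in seq_len(nrow(config$env_spec))) {
    spec <- config$env_spec[r, ]
    zone_off <- rnorm(config$n_zones, 0, spec$zone_sd)
    env[[spec$predictor]] <- spec$mean + zone_off[match(zones, unique(zones))] +
      rnorm(config$n_pops, 0, spec$sd)
  }
  predictors <- config$env_spec$predictor

  ## --- per-individual allele frequency matrix (n x L)
  freq <- outer(q_sativa, anc$freq_a) + outer(1 - q_sativa, anc$freq_b)

  adaptive <- data.frame(locus_index = integer(0), locus_id = character(0),
                         predictor = character(0), slope = numeric(0),
                         base_freq = numeric(0))
  if (config$n_adaptive > 0) {
    adx <- sort(sample.int(L, config$n_adaptive))
    pred_for <- predictors[rep_len(seq_along(predictors), config$n_adaptive)]
    p0 <- pmin(pmax(anc$base_freq[adx], 0.2), 0.8)
    adaptive <- data.frame(locus_index = adx, locus_id = loci$id[adx],
                           predictor = pred_for,
                           slope = rep(config$adaptive_slope, config$n_adaptive),
                           base_freq = p0)
    for (j in seq_along(adx)) {
      x <- env[[pred_for[j]]]
      zstd <- (x - mean(x)) / sd(x)
      site_freq <- plogis(qlogis(p0[j]) + config$adaptive_slope * zstd)
      freq[, adx[j]] <- site_freq[match(individuals$site, env$site)]
    }
  }

  ## --- haplotypes with exponential block boundaries
  dosages <- matrix(0, n, L)
  chrom_start <- c(1, cumsum(per_chrom)[-config$n_chrom] + 1)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      hap <- numeric(L)
      for (cidx in seq_len(config$n_chrom)) {
        idx <- chrom_start[cidx]:(chrom_start[cidx] + per_chrom[cidx] - 1)
        cl <- config$chrom_length_bp
        nb <- ceiling(cl / config$block_len_bp) + 50
        bounds <- cumsum(rexp(nb, rate = 1 / config$block_len_bp))
        while (bounds[length(bounds)] < cl) {
          bounds <- c(bounds, bounds[length(bounds)] +
                        cumsum(rexp(nb, rate = 1 / config$block_len_bp)))
        }
        block <- findInterval(pos[idx], bounds) + 1L
        u <- runif(max(block))
        hap[idx] <- as.numeric(u[block] < freq[i, idx])
      }
      dosages[i, ] <- dosages[i, ] + hap
    }
  }

  if (config$missing_rate > 0) {
    dosages[runif(n * L) < config$missing_rate] <- NA
  }

  G <- genotype_matrix(dosages, loci, individuals)

  ## --- phenotypes: affine in sativa ancestry plus noise
  phenotypes <- data.frame(id = individuals$id)
  for (r in seq_len(nrow(config$pheno_spec))) {
    spec <- config$pheno_spec[r, ]
    phenotypes[[spec$trait]] <- spec$intercept + spec$slope * q_sativa +
      rnorm(n, 0, spec$noise_sd)
  }

  true_Q <- cbind(sativa = q_sativa, falcata = 1 - q_sativa)
  rownames(true_Q) <- individuals$id

  list(
    genotypes = G, env = env, phenotypes = phenotypes,
    truth = list(true_Q = true_Q, adaptive_loci = adaptive,
                 block_len_bp = config$block_len_bp,
                 pheno_slopes = setNames(config$pheno_spec$slope,
                                         config$pheno_spec$trait),
                 freq_a = anc$freq_a, freq_b = anc$freq_b,
                 pop_mean_ancestry = setNames(pop_mean, pop_names))
  )
}

#' Simulate a daily min/max temperature series
#'
#' Seasonal sinusoid plus optional noise; `tmax` and `tmin` are the daily
#' midpoint plus/minus half the diurnal range, so `tmax >= tmin` always.
#'
#' @param n_days series length in days.
#' @param mean annual mean temperature (deg C).
#' @param amplitude seasonal sinusoid amplitude (deg C).
#' @param diurnal_range constant day-night spread (deg C, >= 0).
#' @param noise_sd SD of day-to-day noise on the midpoint (deg C).
#' @param seed RNG seed.
#' @return data.frame with columns `day`, `tmax`, `tmin`.
#' @export
simulate_temperature_series <- function(n_days, mean = 15, amplitude = 10,
                                        diurnal_range = 6, noise_sd = 1.5,
                                        seed = 1) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (diurnal_range < 0) stop("diurnal_range must be >= 0")
  set.seed(seed)
  day <- seq_len(n_days)
  mid <- mean + amplitude * sin(2 * pi * (day - 80) / 365) +
    rnorm(n_days, 0, noise_sd)
  data.frame(day = day, tmax = mid + diurnal_range / 2,
             tmin = mid - diurnal_range / 2)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits VCF 4.2, a dosage TSV, the site environment TSV, the phenotype
#' TSV and the ground truth as JSON.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "dosages.tsv"),
    env = file.path(dir, "env.tsv"),
    pheno = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(dataset$genotypes, paths[["vcf"]])
  write_dosage_tsv(dataset$genotypes, paths[["dosage"]])
  write.table(dataset$env, paths[["env"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$phenotypes, paths[["pheno"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- dataset$truth
  truth$true_Q <- cbind(data.frame(id = rownames(truth$true_Q)),
                        as.data.frame(truth$true_Q))
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
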