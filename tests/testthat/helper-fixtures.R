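# Shared fixtures and independent oracles used across test files.

# tiny genotype matrix built by hand
tiny_genotypes <- function(dosages, chrom = NULL, pos = NULL,
                           population = NULL, site = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); L <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  if (is.null(population)) population <- rep("popA", n)
  if (is.null(site)) site <- population
  genotype_matrix(
    dosages,
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
    data.frame(id = sprintf("ind%02d", seq_len(n)),
               population = population, site = site)
  )
}

# small default simulation used by several files (kept cheap)
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_pops = 8, n_per_pop = 8, n_loci = 400, n_chrom = 2,
         chrom_length_bp = 4e5, n_adaptive = 0, seed = seed),
    list(...))
  simulate_dataset(do.call(sim_config, args))
}

# Weir & Cockerham (1984) two-population FST moment estimator from dosages;
# independent of the generator internals
wc_fst <- function(dos1, dos2) {
  p1 <- colMeans(dos1) / 2
  p2 <- colMeans(dos2) / 2
  n1 <- nrow(dos1); n2 <- nrow(dos2)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  h1 <- colMeans(dos1 == 1); h2 <- colMeans(dos2 == 1)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  sum(a) / sum(a + b + c_)
}

# brute-force Tukey-Kramer pairwise significance matrix, written from
# first principles (means, pooled MSE, studentized range) and independent
# of anova_tukey()
tukey_pairwise_oracle <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n_g <- as.numeric(table(groups))
  means <- tapply(values, groups, mean)
  dfe <- length(values) - k
  mse <- sum((values - means[groups])^2) / dfe
  sig <- matrix(FALSE, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / n_g[i] + 1 / n_g[j]))
      q <- abs(means[i] - means[j]) / se
      sig[i, j] <- sig[j, i] <-
        stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE) < alpha
    }
  }
  sig
}

# letters -> "shares a letter" matrix
share_matrix <- function(letters_vec) {
  k <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  m <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
    }
  }
  m
}

# align a 2-column Q to a reference under column permutation
q_mae <- function(Q, ref) {
  min(mean(abs(Q - ref)), mean(abs(Q[, 2:1] - ref)))
}
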