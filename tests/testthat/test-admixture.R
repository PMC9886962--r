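test_that("admixture log-likelihood matches a direct binomial sum and degenerate cases", {
  set.seed(21)
  d <- matrix(sample(c(0, 1, 2), 60, replace = TRUE), 6, 10)
  # K = 1 with P at the observed frequencies equals the independent
  # binomial log-likelihood computed directly
  pobs <- colMeans(d) / 2
  pobs <- pmin(pmax(pobs, 1e-6), 1 - 1e-6)
  Q <- matrix(1, 6, 1)
  direct <- sum(t(d) * log(pobs) + (2 - t(d)) * log(1 - pobs))
  expect_equal(admixture_loglik(d, Q, matrix(pobs, 1)), direct, tolerance = 1e-10)

  # all-missing matrix: empty sum
  dm <- matrix(NA_real_, 3, 4)
  expect_equal(admixture_loglik(dm, matrix(1, 3, 1), matrix(0.5, 1, 4)), 0)

  # degenerate mixture row (1, 0) uses only the first ancestry's P row
  P <- rbind(runif(10, 0.2, 0.8), runif(10, 0.2, 0.8))
  Q2 <- cbind(rep(1, 6), rep(0, 6))
  expect_equal(admixture_loglik(d, Q2, P),
               admixture_loglik(d, matrix(1, 6, 1), P[1, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("EM solves the separable two-population case and K = 1 in closed form", {
  # two populations fixed for opposite alleles: Q converges to identity
  d <- rbind(matrix(0, 5, 40), matrix(2, 5, 40))
  fit <- fit_admixture(d, K = 2, seed = 2, n_init = 3)
  Qr <- fit$Q
  if (Qr[1, 1] < 0.5) Qr <- Qr[, 2:1]
  target <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                  matrix(c(0, 1), 5, 2, byrow = TRUE))
  expect_lt(max(abs(Qr - target)), 0.01)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-8))

  # K = 1 closed form: Q all ones, P = observed frequencies
  set.seed(5)
  d2 <- matrix(sample(c(0, 1, 2), 50, replace = TRUE), 5, 10)
  f1 <- fit_admixture(d2, K = 1)
  expect_equal(unname(f1$Q), matrix(1, 5, 1))
  expect_equal(as.numeric(f1$P), colMeans(d2) / 2, tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and reaches the grid-search optimum on a tiny instance", {
  # 3 individuals x 2 loci, K = 2: compare against an independent coarse
  # grid over P (step 0.05) with a fine per-individual q grid (step 0.01)
  d <- rbind(c(0, 2), c(1, 1), c(2, 0))
  fit <- fit_admixture(d, K = 2, seed = 7, n_init = 5, tol = 1e-10,
                       max_iter = 5000)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))

  qs <- seq(0, 1, by = 0.01)
  ps <- seq(0.01, 0.99, by = 0.05)
  grid_best <- -Inf
  for (p11 in ps) for (p12 in ps) for (p21 in ps) for (p22 in ps) {
    P <- rbind(c(p11, p12), c(p21, p22))
    ll <- 0
    for (i in 1:3) {
      f <- outer(qs, P[1, ]) + outer(1 - qs, P[2, ])  # 101 x 2
      lli <- f
      lli[] <- d[i, ][col(f)] * log(f) + (2 - d[i, ][col(f)]) * log(1 - f)
      ll <- ll + max(rowSums(lli))
    }
    if (ll > grid_best) grid_best <- ll
  }
  expect_gte(fit$loglik, grid_best - 1e-3)
})

test_that("EM recovers planted admixture proportions", {
  ds <- small_sim(seed = 13, n_pops = 12, n_per_pop = 12, n_loci = 1000,
                  chrom_length_bp = 2e6, fst = 0.3)
  fit <- fit_admixture(ds$genotypes, K = 2, seed = 1, n_init = 2,
                       tol = 1e-4, max_iter = 300)
  expect_lt(q_mae(fit$Q, ds$truth$true_Q), 0.05)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("EM handles missing dosages via the observed-data likelihood", {
  ds <- small_sim(seed = 14, n_pops = 6, n_per_pop = 10, n_loci = 400,
                  missing_rate = 0.15)
  fit <- fit_admixture(ds$genotypes, K = 2, seed = 1, n_init = 2,
                       tol = 1e-4, max_iter = 300)
  expect_true(all(is.finite(fit$Q)))
  expect_lt(q_mae(fit$Q, ds$truth$true_Q), 0.08)
})

test_that("Evanno delta-K follows the second-difference formula and edge rules", {
  # hand arithmetic: means (-1000, -800, -795, -794)
  means <- c(-1000, -800, -795, -794)
  sds <- c(1, 2, 1.5, 1)
  set.seed(3)
  runs <- sapply(1:4, function(j) means[j] + sds[j] * scale(rnorm(6))[, 1])
  colnames(runs) <- 1:4
  ev <- evanno_delta_k(runs)
  m <- colMeans(runs); s <- apply(runs, 2, sd)
  expect_equal(ev$table$delta_k[2], abs(m[3] - 2 * m[2] + m[1]) / s[2],
               ignore_attr = TRUE)
  expect_equal(ev$table$delta_k[3], abs(m[4] - 2 * m[3] + m[2]) / s[3],
               ignore_attr = TRUE)
  expect_true(is.na(ev$table$delta_k[1]) && is.na(ev$table$delta_k[4]))
  expect_equal(ev$k_star, 2)

  # linear mean trajectory: all interior delta-K are zero
  lin <- sapply(1:4, function(j) -100 * j + c(-0.5, 0.5, -0.25, 0.25))
  colnames(lin) <- 1:4
  ev2 <- evanno_delta_k(lin)
  expect_equal(ev2$table$delta_k[2:3], c(0, 0))

  # zero SD at an interior K is excluded with a warning
  z <- cbind(`1` = c(-10, -11), `2` = c(-5, -5), `3` = c(-4, -4.5))
  w <- capture_warnings(ev3 <- evanno_delta_k(z))
  expect_match(w, "zero", all = FALSE)
  expect_true(is.na(ev3$k_star))
})

test_that("run alignment is permutation-invariant and the consensus beats single runs", {
  set.seed(17)
  Q <- matrix(rgamma(40, 2), 20, 2)
  Q <- Q / rowSums(Q)

  # single run: itself
  expect_equal(align_runs(list(Q)), Q)

  # identical run with swapped columns: consensus equals run 1
  expect_equal(align_runs(list(Q, Q[, 2:1])), Q, tolerance = 1e-12)

  # noisy perturbations: consensus closer (Frobenius) to truth than any run
  perturb <- function(s) {
    set.seed(s)
    Qp <- pmin(pmax(Q + matrix(rnorm(40, 0, 0.08), 20, 2), 1e-6), 1)
    Qp <- Qp / rowSums(Qp)
    Qp[, sample(2)]
  }
  runs <- lapply(1:3, perturb)
  cons <- align_runs(runs)
  frob <- function(A) sqrt(sum((A - Q)^2))
  ferr <- function(A) min(frob(A), frob(A[, 2:1]))  # orientation-free
  run_err <- vapply(runs, ferr, numeric(1))
  expect_lt(ferr(cons), min(run_err))
})

test_that("parentage classification applies the strict >50% rule", {
  Q <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(0.84, 0.16), c(0.34, 0.66))
  colnames(Q) <- c("sativa", "falcata")
  lab <- classify_by_parentage(Q, "sativa")
  expect_equal(as.character(lab), c("sativa", "falcata", "sativa", "falcata"))
  # the exactly-at-threshold individual is flagged
  expect_equal(attr(lab, "boundary"), 2L)
})
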