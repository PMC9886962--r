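test_that("predictor screening drops correlated members and exact collinears", {
  set.seed(2)
  n <- 20
  pH <- rnorm(n)
  EC <- 0.95 * pH + rnorm(n, 0, sqrt(1 - 0.95^2))  # |r| > 0.7 with pH
  K <- rnorm(n)
  E <- data.frame(site = paste0("s", 1:n), pH = pH, EC = EC, K = K)
  res <- screen_predictors(E)
  expect_false("EC" %in% names(res$env))   # later-listed member dropped
  expect_true(all(c("pH", "K") %in% names(res$env)))
  expect_equal(res$report$reason[1], "high_correlation")

  # orthogonal predictors: nothing dropped, VIF = 1
  Eo <- data.frame(site = paste0("s", 1:4),
                   a = c(1, 1, -1, -1), b = c(1, -1, 1, -1),
                   c = c(1, -1, -1, 1))
  reso <- screen_predictors(Eo)
  expect_equal(nrow(reso$report), 0)
  expect_equal(unname(reso$vif), rep(1, 3), tolerance = 1e-12)

  # exact linear dependence (components exactly orthogonal, so each pair
  # has |r| = 0 or 1/sqrt(3) < 0.7 and survives the correlation screen):
  # infinite VIF, dropped
  set.seed(3)
  M <- scale(matrix(rnorm(120), 40, 3), scale = FALSE)
  Qo <- qr.Q(qr(M))
  Ec <- data.frame(site = paste0("s", 1:40), a = Qo[, 1], b = Qo[, 2],
                   c = Qo[, 3], s = rowSums(Qo))
  resc <- screen_predictors(Ec)
  expect_true("high_vif" %in% resc$report$reason)
  expect_equal(length(setdiff(names(resc$env), "site")), 3)

  # constant predictor dropped with warning
  Ek <- data.frame(site = paste0("s", 1:5), a = rnorm(5), k = rep(1, 5))
  expect_warning(resk <- screen_predictors(Ek), "constant")
  expect_false("k" %in% names(resk$env))
})

test_that("RDA fitted values equal per-locus OLS fits; single predictor has rank 1", {
  set.seed(6)
  n <- 50; L <- 200; p <- 4
  Y <- matrix(rnorm(n * L), n, L)
  X <- matrix(rnorm(n * p), n, p)
  mod <- rda_fit(Y, X)
  Xs <- scale(X)
  maxdiff <- 0
  for (j in seq_len(L)) {
    ols <- lm.fit(cbind(1, Xs), Y[, j])
    maxdiff <- max(maxdiff, max(abs((ols$fitted.values - mean(Y[, j])) -
                                      mod$Yfit[, j])))
  }
  expect_lt(maxdiff, 1e-8)
  expect_true(all(diff(mod$eigenvalues) <= 1e-12))
  # loadings columns orthonormal
  expect_equal(crossprod(mod$loadings), diag(mod$rank), tolerance = 1e-8,
               ignore_attr = TRUE)

  # constant Y: all eigenvalues vanish (rank 0 fitted matrix)
  Y0 <- matrix(5, n, 10)
  mod0 <- rda_fit(Y0, X)
  expect_equal(mod0$rank, 0)

  # single predictor: one nonzero eigenvalue, loadings proportional to
  # the per-locus simple-regression slopes
  X1 <- matrix(rnorm(n), n, 1)
  mod1 <- rda_fit(Y, X1)
  expect_equal(mod1$rank, 1)
  slopes <- as.numeric(cov(Y, scale(X1))) / var(as.numeric(scale(X1)))
  v <- mod1$loadings[, 1]
  expect_gt(abs(cor(v, slopes)), 1 - 1e-10)
})

test_that("axis selection: broken stick, fixed and proportion modes", {
  expect_equal(select_axes(c(10, 0, 0)), 1)
  expect_equal(select_axes(c(5, 4, 1), method = "fixed:2"), 2)
  expect_equal(select_axes(c(5, 4, 1), method = "proportion:0.89"), 2)

  # equal eigenvalues against the closed-form broken-stick expectation
  eig <- c(1, 1, 1, 1)
  p <- 4
  bs <- rev(cumsum(1 / rev(seq_len(p)))) / p
  expected_k <- if (0.25 > bs[1]) NA else 1  # share 0.25 < b1 -> floor K = 1
  expect_equal(select_axes(eig), 1)
  expect_true(0.25 < bs[1])  # confirms the oracle arithmetic behind the case

  # a dominant axis pattern where axes 1-2 beat the stick
  eig2 <- c(6, 3, 0.5, 0.5)
  share <- eig2 / sum(eig2)
  above <- share > bs
  k_oracle <- which(!above)[1] - 1
  expect_equal(select_axes(eig2), k_oracle)
})

test_that("robust center/cov agrees with classical on clean data and resists contamination", {
  set.seed(9)
  L <- 5000
  Z <- matrix(rnorm(L * 2), L, 2) %*% chol(matrix(c(1, 0.3, 0.3, 0.8), 2))
  rob <- robust_center_cov(Z, method = "mcd", seed = 1)
  cls <- robust_center_cov(Z, method = "classical")
  relF <- norm(rob$cov - cls$cov, "F") / norm(cls$cov, "F")
  expect_lt(relF, 0.1)
  expect_lt(max(abs(rob$center - cls$center)), 0.1)

  # 10% planted extreme loadings: robust determinant <= classical
  Zc <- Z
  idx <- sample(L, L / 10)
  Zc[idx, ] <- Zc[idx, ] + 15
  robc <- robust_center_cov(Zc, method = "mcd", seed = 1)
  clsc <- robust_center_cov(Zc, method = "classical")
  expect_lte(det(robc$cov), det(clsc$cov))

  # K = 1 reduces to robust location/scale and D2 = ((x - mu)/sigma)^2
  z1 <- matrix(rnorm(2000), ncol = 1)
  r1 <- robust_center_cov(z1, method = "mcd")
  d2 <- mahalanobis_d2(z1, r1$center, r1$cov)
  expect_equal(d2, as.numeric((z1 - r1$center)^2 / r1$cov[1, 1]),
               tolerance = 1e-12)
  expect_lt(abs(r1$cov[1, 1] - 1), 0.15)  # consistency at the normal model
})

test_that("Mahalanobis distances match the direct solve-based formula", {
  expect_equal(mahalanobis_d2(matrix(c(0, 0), 1), c(0, 0), diag(2)), 0,
               ignore_attr = TRUE)
  expect_equal(mahalanobis_d2(matrix(c(3, 4), 1), c(0, 0), diag(2)), 25,
               ignore_attr = TRUE)
  set.seed(12)
  for (rep in 1:5) {
    K <- sample(2:4, 1)
    Z <- matrix(rnorm(200 * K), 200, K)
    A <- crossprod(matrix(rnorm(K * K), K)) + diag(K) * 0.1
    mu <- rnorm(K)
    d2 <- mahalanobis_d2(Z, mu, A)
    oracle <- apply(Z, 1, function(z) {
      dz <- z - mu
      sum(dz * solve(A, dz))
    })
    expect_equal(d2, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("genomic inflation factor: closed form, null sampling, scale equivariance", {
  expect_equal(genomic_inflation(c(1, 2, 3), K = 2), 2 / (2 * log(2)),
               tolerance = 1e-12)
  expect_equal(2 / (2 * log(2)), 1.4427, tolerance = 1e-4)
  set.seed(15)
  d2 <- rchisq(10000, df = 3)
  expect_lt(abs(genomic_inflation(d2, K = 3) - 1), 0.05)
  expect_equal(genomic_inflation(d2 * 2.5, K = 3),
               2.5 * genomic_inflation(d2, K = 3), tolerance = 1e-12)
})

test_that("p-values and q-values behave at the boundaries and match hand BH", {
  expect_equal(scan_pvalues(0, lambda = 1, K = 2), 1)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(qvalues(p, method = "bh"), rep(0.04, 4))
  # q order-compatible with p; outliers strict
  set.seed(1)
  pv <- runif(200)
  q <- qvalues(pv, method = "storey")
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(pv)]) >= -1e-12))
  expect_equal(call_outliers(c(0.005, 0.01, 0.02), 0.01),
               c(TRUE, FALSE, FALSE))
})

test_that("dosage-environment correlations match the direct formula", {
  G <- tiny_genotypes(cbind(c(0, 1, 2), c(1, 1, 1)),
                      population = c("s1", "s2", "s3"))
  E <- as_env_table(data.frame(site = c("s1", "s2", "s3"),
                               env = c(1, 2, 3), flat = c(2, 2, 2)))
  r <- snp_env_correlation(G, E)
  expect_equal(r[1, "env"], 1)
  expect_true(is.na(r[2, "env"]))     # zero-variance dosage
  expect_true(all(is.na(r[, "flat"])))  # zero-variance predictor

  set.seed(20)
  d <- matrix(sample(0:2, 60, replace = TRUE), 12, 5)
  sites <- paste0("s", rep(1:4, each = 3))
  G2 <- tiny_genotypes(d, population = sites)
  vals <- rnorm(4)
  E2 <- as_env_table(data.frame(site = paste0("s", 1:4), env = vals))
  r2 <- snp_env_correlation(G2, E2)
  x <- vals[rep(1:4, each = 3)]
  for (j in 1:5) {
    expected <- suppressWarnings(cor(d[, j], x))
    if (is.na(expected)) expect_true(is.na(r2[j, 1]))
    else expect_equal(r2[j, 1], expected, tolerance = 1e-12,
                      ignore_attr = TRUE)
  }
})

test_that("candidate mapping respects inclusive boundaries and intergenic labels", {
  ann <- data.frame(chrom = "chr1", start = 100, end = 200,
                    gene_id = "g1", annotation = "desc")
  class(ann) <- c("gene_annotation", "data.frame")
  hits <- data.frame(chrom = "chr1", pos = c(150, 200, 100, 250))
  out <- map_candidates(hits, ann)
  expect_equal(out$gene_id, c("g1", "g1", "g1", "Intergenic region"))

  # absent chromosome: warning, intergenic
  hits2 <- data.frame(chrom = "chr9", pos = 5)
  expect_warning(out2 <- map_candidates(hits2, ann), "chr9")
  expect_equal(out2$gene_id, "Intergenic region")
})

test_that("scan statistics are invariant to individual order and equivariant to locus order", {
  ds <- small_sim(seed = 77, n_pops = 8, n_per_pop = 8, n_loci = 300,
                  n_adaptive = 5, adaptive_slope = 1.5)
  Gi <- impute_mean_dosage(maf_filter(ds$genotypes)$genotypes)
  scan <- rda_scan(Gi, ds$env, axes = "fixed:2", robust = "classical")

  set.seed(2)
  perm <- sample(n_ind(Gi))
  Gp <- Gi[perm, ]
  scan_p <- rda_scan(Gp, ds$env, axes = "fixed:2", robust = "classical")
  expect_equal(scan_p$table$d2, scan$table$d2, tolerance = 1e-8)
  expect_equal(scan_p$table$q, scan$table$q, tolerance = 1e-8)

  permL <- sample(n_loci(Gi))
  Gl <- Gi[, permL]
  scan_l <- rda_scan(Gl, ds$env, axes = "fixed:2", robust = "classical")
  expect_equal(scan_l$table$d2, scan$table$d2[permL], tolerance = 1e-8)
})

test_that("the full scan with classical covariance matches a transparent reference implementation", {
  # one-function dense-algebra reference for the whole pipeline
  reference_scan <- function(Y, X, K) {
    Yc <- scale(Y, scale = FALSE)
    Xs <- scale(X)
    B <- solve(t(Xs) %*% Xs) %*% t(Xs) %*% Yc
    Yfit <- Xs %*% B
    sv <- svd(Yfit)
    V <- sv$v[, seq_len(K), drop = FALSE]
    mu <- colMeans(V)
    S <- stats::cov(V)
    d2 <- numeric(ncol(Y))
    for (l in seq_len(ncol(Y))) {
      dz <- V[l, ] - mu
      d2[l] <- sum(dz * solve(S, dz))
    }
    lam <- median(d2) / qchisq(0.5, K)
    p <- pchisq(d2 / lam, K, lower.tail = FALSE)
    list(d2 = d2, lambda = lam, p = p)
  }
  ds <- small_sim(seed = 55, n_pops = 9, n_per_pop = 6, n_loci = 150)
  Gi <- impute_mean_dosage(ds$genotypes)
  E <- as_env_table(ds$env)
  preds <- setdiff(names(E), "site")
  X <- sapply(preds, function(p) E[[p]][match(Gi$individuals$site, E$site)])
  scan <- rda_scan(Gi, E, axes = "fixed:2", robust = "classical",
                   qmethod = "bh", screen = FALSE)
  ref <- reference_scan(Gi$dosages, X, K = 2)
  expect_equal(scan$table$d2, ref$d2, tolerance = 1e-8)
  expect_equal(scan$lambda, ref$lambda, tolerance = 1e-8)
  expect_equal(scan$table$p, ref$p, tolerance = 1e-8)
})
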