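#' Screen environmental predictors for collinearity
#'
#' Two-stage screen used before a regression-based GEA: (1) while any
#' predictor pair has `|Pearson r| > r_max`, the later-listed member of
#' the first offending pair is dropped (the conventional `|r| > 0.7`
#' rule); (2) variance inflation factors `VIF = 1 / (1 - R^2)` of each
#' survivor regressed on the rest are computed and predictors with
#' `VIF > vif_max` are dropped iteratively, largest first (the
#' conventional cutoff is 5). Constant predictors have undefined
#' correlation and are dropped up front with a warning.
#'
#' @param E an `env_table` (or data.frame with `site` plus numeric
#'   predictors).
#' @param r_max pairwise correlation cutoff.
#' @param vif_max VIF cutoff.
#' @return list: `env` (screened table), `report` (data.frame
#'   `predictor`, `reason`, `value`), `vif` (named vector for survivors).
#' @export
screen_predictors <- function(E, r_max = 0.7, vif_max = 5) {
  E <- as_env_table(E)
  if (nrow(E) < 2) stop("need at least two sites")
  preds <- env_predictors(E)
  report <- data.frame(predictor = character(0), reason = character(0),
                       value = numeric(0))
  const <- preds[vapply(preds, function(p) sd(E[[p]]) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant predictor(s): ", paste(const, collapse = ", "))
    report <- rbind(report, data.frame(predictor = const, reason = "constant",
                                       value = NA_real_))
    preds <- setdiff(preds, const)
  }
  repeat {
    if (length(preds) < 2) break
    cm <- cor(E[preds])
    cm[!upper.tri(cm)] <- 0
    off <- which(abs(cm) > r_max, arr.ind = TRUE)
    if (nrow(off) == 0) break
    off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
    drop_idx <- max(off[1, ])  # later-listed member of the first pair
    report <- rbind(report, data.frame(
      predictor = preds[drop_idx], reason = "high_correlation",
      value = cm[off[1, 1], off[1, 2]]))
    preds <- preds[-drop_idx]
  }
  vif <- compute_vif(E, preds)
  while (length(preds) > 1 && any(vif > vif_max)) {
    worst <- which.max(vif)
    report <- rbind(report, data.frame(predictor = preds[worst],
                                       reason = "high_vif",
                                       value = vif[worst]))
    preds <- preds[-worst]
    vif <- compute_vif(E, preds)
  }
  out <- E[, c("site", preds), drop = FALSE]
  attr(out, "metadata") <- attr(E, "metadata")
  class(out) <- c("env_table", "data.frame")
  list(env = out, report = report, vif = vif)
}

compute_vif <- function(E, preds) {
  if (length(preds) < 2) return(setNames(rep(1, length(preds)), preds))
  vapply(preds, function(p) {
    fit <- lm(stats::reformulate(preds[preds != p], response = p),
              data = as.data.frame(E))
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Fit a redundancy analysis (RDA) of genotypes on environment
#'
#' Multivariate regression of the centered dosage matrix `Y` (individuals
#' x loci) on the standardized predictor matrix `X` (site values
#' broadcast to individuals), followed by a PCA of the fitted values:
#' `B = (X'X)^-1 X'Y`, `Y' = XB`, and the SVD of `Y'` yields the
#' constrained axes. Eigenvalues are squared singular values divided by
#' `n - 1`; locus loadings are the right singular vectors (orthonormal
#' columns).
#'
#' @param G a [genotype_matrix()] without missing cells (impute first),
#'   or a plain numeric matrix.
#' @param E an `env_table` covering every site in `G`; or a numeric
#'   matrix already expanded to individuals.
#' @return object of class `rda_model`: `X` (standardized), `B`,
#'   `eigenvalues`, `loadings` (loci x axes), `scores` (individuals x
#'   axes), `Yfit`, `rank`.
#' @export
rda_fit <- function(G, E) {
  if (inherits(G, "genotype_matrix")) {
    Y <- G$dosages
    if (anyNA(Y)) stop("missing dosages: run impute_mean_dosage() first")
    if (is.data.frame(E) || inherits(E, "env_table")) {
      E <- as_env_table(E)
      preds <- env_predictors(E)
      X <- vapply(preds, function(p) {
        broadcast_to_individuals(E[[p]], E$site, G)
      }, numeric(n_ind(G)))
      colnames(X) <- preds
    } else {
      X <- as.matrix(E)
    }
  } else {
    Y <- as.matrix(G)
    X <- as.matrix(E)
  }
  n <- nrow(Y); p <- ncol(X)
  if (n < p + 2) stop("need n individuals >= p + 2 predictors")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X, center = TRUE, scale = TRUE)
  if (any(!is.finite(Xs))) stop("constant predictor: run screen_predictors() first")
  XtX <- crossprod(Xs)
  B <- tryCatch(solve(XtX, crossprod(Xs, Yc)), error = function(e) {
    stop("singular predictor cross-product; remove collinear predictors ",
         "with screen_predictors()")
  })
  Yfit <- Xs %*% B
  # economy SVD via the n x n cross-product (L is usually >> n)
  ee <- eigen(tcrossprod(Yfit), symmetric = TRUE)
  pos <- ee$values > max(ee$values, 0) * 1e-12 & ee$values > 0
  d <- sqrt(ee$values[pos])
  U <- ee$vectors[, pos, drop = FALSE]
  V <- crossprod(Yfit, U) %*% diag(1 / d, nrow = length(d))
  structure(list(
    X = Xs, B = B, eigenvalues = d^2 / (n - 1),
    loadings = V, scores = U %*% diag(d, nrow = length(d)),
    Yfit = Yfit, rank = length(d)
  ), class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: %d constrained axes, eigenvalues %s\n", x$rank,
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' Choose the number of retained constrained axes
#'
#' Mechanized version of the "look at the information retained per axis"
#' judgement: the default broken-stick rule retains the leading axes
#' whose eigenvalue share exceeds the broken-stick expectation
#' `b_j = (1/p) * sum_{i=j}^{p} 1/i`, stopping at the first failure.
#' `"fixed:K"` and `"proportion:x"` (smallest K whose cumulative share
#' reaches `x`) are available as overrides. At least one axis is always
#' retained.
#'
#' @param eigenvalues non-increasing, non-negative vector.
#' @param method `"broken_stick"`, `"fixed:K"` or `"proportion:x"`.
#' @return integer K >= 1.
#' @export
select_axes <- function(eigenvalues, method = "broken_stick") {
  stopifnot(length(eigenvalues) >= 1)
  if (startsWith(method, "fixed:")) {
    k <- as.integer(sub("fixed:", "", method))
    return(max(1L, min(k, length(eigenvalues))))
  }
  if (startsWith(method, "proportion:")) {
    x <- as.numeric(sub("proportion:", "", method))
    cum <- cumsum(eigenvalues) / sum(eigenvalues)
    return(max(1L, min(which(cum >= x))))
  }
  if (method != "broken_stick") stop("unknown method: ", method)
  p <- length(eigenvalues)
  bs <- rev(cumsum(1 / rev(seq_len(p)))) / p
  share <- eigenvalues / sum(eigenvalues)
  above <- share > bs
  k <- if (!above[1]) 1L else {
    first_fail <- which(!above)
    if (length(first_fail) == 0) p else first_fail[1] - 1L
  }
  max(1L, as.integer(k))
}

#' Robust center and covariance of the locus-loading cloud
#'
#' Minimum Covariance Determinant estimate (FAST-MCD, subset fraction
#' `h = 0.75`) of the location and scatter of the loadings, so that a
#' minority of outlying loci does not inflate the Mahalanobis metric they
#' are judged against. A classical mean/covariance mode is available for
#' reference computations. For a single axis an exact univariate MCD
#' (minimum-variance contiguous half) is used, scaled by the usual
#' normal-model consistency factor.
#'
#' @param loadings loci x K matrix (`L > 5 K` recommended).
#' @param method `"mcd"` or `"classical"`.
#' @param h MCD subset fraction.
#' @param seed RNG seed for the MCD subsampling.
#' @return list with `center` (length-K) and `cov` (K x K). A singular
#'   scatter gets a ridge of 1e-8 with a warning.
#' @export
robust_center_cov <- function(loadings, method = c("mcd", "classical"),
                              h = 0.75, seed = 1) {
  method <- match.arg(method)
  Z <- as.matrix(loadings)
  L <- nrow(Z); K <- ncol(Z)
  if (method == "classical") {
    out <- list(center = colMeans(Z), cov = cov(Z))
  } else {
    if (K == 1) {
      out <- mcd_1d(Z[, 1], h)
    } else {
      set.seed(seed)
      r <- MASS::cov.rob(Z, method = "mcd",
                         quantile.used = floor(h * L), nsamp = "sample")
      out <- list(center = r$center, cov = r$cov)
    }
    # standard FAST-MCD reweighting: refit on points within the 97.5%
    # chi-squared envelope of the raw estimate, then rescale for the
    # trimming so the estimate is consistent at the normal model
    d2 <- mahalanobis(Z, out$center, out$cov)
    w <- d2 <= qchisq(0.975, df = K)
    if (sum(w) > K + 1) {
      Zw <- Z[w, , drop = FALSE]
      cfac <- 0.975 / pchisq(qchisq(0.975, df = K), df = K + 2)
      out <- list(center = colMeans(Zw), cov = cov(Zw) * cfac)
    }
  }
  ev <- eigen(out$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(abs(ev), 1)) {
    warning("singular scatter matrix; adding ridge 1e-8")
    out$cov <- out$cov + diag(1e-8, K)
  }
  out
}

# exact 1-D MCD: contiguous half with smallest variance, consistency-scaled
mcd_1d <- function(x, h = 0.75) {
  n <- length(x)
  hsize <- max(2, floor(h * n))
  xs <- sort(x)
  best_var <- Inf; best_mu <- mean(xs)
  for (s in seq_len(n - hsize + 1)) {
    w <- xs[s:(s + hsize - 1)]
    v <- var(w)
    if (v < best_var) { best_var <- v; best_mu <- mean(w) }
  }
  alpha <- hsize / n
  cfac <- alpha / pchisq(qchisq(alpha, df = 1), df = 3)
  list(center = best_mu, cov = matrix(best_var * cfac, 1, 1))
}

#' Squared Mahalanobis distance of each locus from the loading center
#'
#' `D2_l = (z_l - mu)' Sigma^-1 (z_l - mu)`.
#'
#' @param loadings loci x K matrix.
#' @param center length-K location.
#' @param cov K x K positive-definite scatter.
#' @return numeric vector of squared distances (>= 0).
#' @export
mahalanobis_d2 <- function(loadings, center, cov) {
  mahalanobis(as.matrix(loadings), center, cov)
}

#' Genomic inflation factor of a chi-squared genome scan
#'
#' `lambda = median(D2) / median(chi2_K)`; for `K = 2` the theoretical
#' median is exactly `2 ln 2`. Dividing the statistics by `lambda`
#' re-anchors the null median at its theoretical value, limiting
#' systematic inflation from confounding (e.g. residual structure).
#'
#' @param d2 squared Mahalanobis distances.
#' @param K retained-axis count (chi-squared degrees of freedom).
#' @return scalar inflation factor.
#' @export
genomic_inflation <- function(d2, K) {
  stopifnot(length(d2) >= 1, K >= 1)
  median(d2) / qchisq(0.5, df = K)
}

#' Inflation-corrected chi-squared p-values
#'
#' @param d2 squared Mahalanobis distances.
#' @param lambda genomic inflation factor (> 0).
#' @param K degrees of freedom.
#' @return upper-tail p-values of `d2 / lambda` under `chi2_K`.
#' @export
scan_pvalues <- function(d2, lambda, K) {
  stopifnot(lambda > 0)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' q-values (FDR) for a vector of p-values
#'
#' `"storey"` (default) estimates the null proportion `pi0` on a lambda
#' grid with cubic-spline smoothing and returns
#' `q_i = pi0 * min_{j: p_j >= p_i} (m * p_j / rank_j)`; with fewer than
#' 50 p-values `pi0` is fixed at 1 (where the grid estimate is
#' unstable), which reduces to Benjamini-Hochberg. `"bh"` is plain
#' Benjamini-Hochberg.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @return q-values, order-compatible with `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  if (method == "bh") return(p.adjust(p, method = "BH"))
  m <- length(p)
  pi0 <- 1
  if (m >= 50) {
    lam <- seq(0.05, 0.9, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- tryCatch(smooth.spline(lam, pi0_lam, df = 3), error = function(e) NULL)
    pi0 <- if (is.null(fit)) min(1, pi0_lam[length(pi0_lam)]) else
      min(1, predict(fit, x = max(lam))$y)
    pi0 <- max(pi0, 1e-3)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[ro]
}

#' Call outlier loci from q-values
#'
#' @param q q-values.
#' @param q_max outlier threshold (default 0.01; a locus is an outlier if
#'   `q < q_max`, strictly).
#' @return logical vector.
#' @export
call_outliers <- function(q, q_max = 0.01) {
  q < q_max
}

#' Pearson correlation between locus dosage and an environmental predictor
#'
#' Each individual carries its site's predictor value; the correlation is
#' computed over individuals with a non-missing dosage. Zero-variance
#' dosages or predictors give `NA` (flagged undefined).
#'
#' @param G a [genotype_matrix()].
#' @param E an `env_table`.
#' @param loci locus indices (default all).
#' @param predictors predictor names (default all).
#' @return loci x predictors matrix of correlations.
#' @export
snp_env_correlation <- function(G, E, loci = NULL, predictors = NULL) {
  E <- as_env_table(E)
  if (is.null(loci)) loci <- seq_len(n_loci(G))
  if (is.null(predictors)) predictors <- env_predictors(E)
  out <- matrix(NA_real_, length(loci), length(predictors),
                dimnames = list(G$loci$id[loci], predictors))
  for (pj in seq_along(predictors)) {
    x <- broadcast_to_individuals(E[[predictors[pj]]], E$site, G)
    if (sd(x) == 0) next  # undefined: constant predictor
    for (li in seq_along(loci)) {
      g <- G$dosages[, loci[li]]
      ok <- !is.na(g)
      if (sum(ok) < 3 || sd(g[ok]) == 0) next
      out[li, pj] <- cor(g[ok], x[ok])
    }
  }
  out
}

#' Map outlier SNPs onto gene annotation intervals
#'
#' A SNP is assigned to every gene interval containing its position
#' (1-based inclusive; both boundary positions count as inside). SNPs
#' contained by no interval get the literal label `"Intergenic region"`.
#' Chromosomes absent from the annotation trigger a warning and their
#' SNPs are intergenic.
#'
#' @param hits data.frame with columns `chrom`, `pos` (plus any others,
#'   carried through), e.g. the outlier rows of an [rda_scan()] result.
#' @param annotation a `gene_annotation` from [read_annotation()].
#' @return data.frame: input columns plus `gene_id` and `annotation`
#'   (one row per SNP-gene pair; intergenic SNPs keep one row).
#' @export
map_candidates <- function(hits, annotation) {
  stopifnot(all(c("chrom", "pos") %in% names(hits)))
  missing_chr <- setdiff(unique(hits$chrom), unique(annotation$chrom))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    inside <- which(annotation$chrom == h$chrom &
                      annotation$start <= h$pos & annotation$end >= h$pos)
    if (length(inside) == 0) {
      cbind(h, data.frame(gene_id = "Intergenic region",
                          annotation = NA_character_))
    } else {
      cbind(h[rep(1, length(inside)), , drop = FALSE],
            data.frame(gene_id = annotation$gene_id[inside],
                       annotation = annotation$annotation[inside]))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RDA genome scan for genotype-environment association
#'
#' The full outlier scan: (optionally screened) predictors are broadcast
#' to individuals and standardized; the RDA is fitted ([rda_fit()]); `K`
#' axes are retained ([select_axes()]); a robust center and scatter of
#' the locus loadings ([robust_center_cov()]) defines squared Mahalanobis
#' distances ([mahalanobis_d2()]), which are rescaled by the genomic
#' inflation factor and referred to `chi2_K` for p-values; q-values
#' control the FDR and loci with `q < q_max` are flagged as outliers.
#' Each locus is also assigned the predictor of maximum `|r|` with its
#' dosage.
#'
#' @param G an imputed [genotype_matrix()].
#' @param E an `env_table`.
#' @param axes axis-retention method for [select_axes()].
#' @param robust `"mcd"` or `"classical"` scatter.
#' @param qmethod `"storey"` or `"bh"`.
#' @param q_max outlier threshold on q.
#' @param screen logical: apply [screen_predictors()] first.
#' @param seed RNG seed (MCD subsampling).
#' @return object of class `rda_scan_result`: data.frame `table` (per
#'   locus: `locus`, `chrom`, `pos`, `d2`, `p`, `q`, `outlier`,
#'   `predictor`, `r`, `neg_log10_p`) plus `model`, `K`, `lambda`,
#'   `center`, `cov`, `env` (the screened table).
#' @export
rda_scan <- function(G, E, axes = "broken_stick", robust = "mcd",
                     qmethod = "storey", q_max = 0.01, screen = TRUE,
                     seed = 1) {
  E <- as_env_table(E)
  screen_report <- NULL
  if (screen) {
    s <- screen_predictors(E)
    E <- s$env
    screen_report <- s$report
  }
  model <- rda_fit(G, E)
  K <- select_axes(model$eigenvalues, method = axes)
  Z <- model$loadings[, seq_len(K), drop = FALSE]
  rc <- robust_center_cov(Z, method = robust, seed = seed)
  d2 <- mahalanobis_d2(Z, rc$center, rc$cov)
  lambda <- genomic_inflation(d2, K)
  p <- scan_pvalues(d2, lambda, K)
  q <- qvalues(p, method = qmethod)
  outlier <- call_outliers(q, q_max = q_max)
  r_all <- snp_env_correlation(G, E)
  best <- apply(r_all, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(abs(r))
  })
  tab <- data.frame(
    locus = G$loci$id, chrom = G$loci$chrom, pos = G$loci$pos,
    d2 = d2, p = p, q = q, outlier = outlier,
    predictor = colnames(r_all)[best],
    r = r_all[cbind(seq_len(nrow(r_all)), best)],
    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
    row.names = NULL
  )
  structure(list(table = tab, model = model, K = K, lambda = lambda,
                 center = rc$center, cov = rc$cov, env = E,
                 correlations = r_all, screen_report = screen_report,
                 q_max = q_max),
            class = "rda_scan_result")
}

#' @export
print.rda_scan_result <- function(x, ...) {
  cat(sprintf(
    "rda_scan_result: %d loci, K = %d axes, lambda = %.3f, %d outliers (q < %g)\n",
    nrow(x$table), x$K, x$lambda, sum(x$table$outlier), x$q_max))
  invisible(x)
}
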