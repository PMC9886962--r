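#' Admixture-model log-likelihood
#'
#' Observed-data log-likelihood of dosages under the admixture model with
#' individual ancestry proportions `Q` (rows on the simplex) and ancestral
#' allele frequencies `P`: with `f_il = sum_k Q_ik P_kl`,
#' `ll = sum_il [ g_il log f_il + (2 - g_il) log(1 - f_il) ]`, skipping
#' missing cells. The binomial coefficient `choose(2, g)` is a constant in
#' the parameters and is omitted throughout (so values are comparable
#' across fits, not across datasets).
#'
#' @param G a [genotype_matrix()] or a dosage matrix (individuals x loci).
#' @param Q individuals x K matrix, rows summing to 1.
#' @param P K x loci matrix of frequencies in (0, 1).
#' @param eps clipping bound applied to `f` (values outside `(eps, 1-eps)`
#'   are clipped with a warning).
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(G, Q, P, eps = 1e-9) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  Q <- as.matrix(Q); P <- as.matrix(P)
  stopifnot(nrow(Q) == nrow(d), ncol(Q) == nrow(P), ncol(P) == ncol(d))
  if (max(abs(rowSums(Q) - 1)) > 1e-6) stop("rows of Q must sum to 1")
  f <- Q %*% P
  if (any(f <= 0 | f >= 1)) {
    warning("mixture frequencies outside (0, 1) clipped at eps")
  }
  f <- pmin(pmax(f, eps), 1 - eps)
  obs <- !is.na(d)
  if (!any(obs)) return(0)
  sum(d[obs] * log(f[obs]) + (2 - d[obs]) * log(1 - f[obs]))
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood analogue of the STRUCTURE admixture model: EM
#' alternates expected per-ancestry allele counts with closed-form updates
#' of `Q` and `P`; the log-likelihood is non-decreasing across iterations.
#' The best of `n_init` seeded restarts is returned. Missing dosages are
#' skipped via the observed-data likelihood, so no imputation is needed
#' (or wanted) here.
#'
#' @param G a [genotype_matrix()] or dosage matrix with integer dosages.
#' @param K number of ancestral populations (>= 1).
#' @param seed RNG seed; restarts use `seed + 1, ..., seed + n_init`.
#' @param n_init number of random restarts.
#' @param tol absolute log-likelihood gain below which EM stops.
#' @param max_iter iteration cap per restart.
#' @return object of class `admixture_fit`: `Q` (rownames = individual
#'   ids), `P`, `loglik`, `K`, `n_iter`, `converged`, and `loglik_trace`
#'   of the winning restart.
#' @export
fit_admixture <- function(G, K, seed = 1, n_init = 5, tol = 1e-6,
                          max_iter = 2000) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  ids <- rownames(d)
  n <- nrow(d); L <- ncol(d)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K must not exceed the number of individuals")
  if (isTRUE(attr(G, "imputed"))) {
    stop("fit_admixture needs integer dosages; pass the unimputed matrix")
  }
  pmin_ <- 1e-9
  pobs <- colMeans(d, na.rm = TRUE) / 2
  pobs[is.nan(pobs)] <- 0.5
  pobs <- pmin(pmax(pobs, 1e-4), 1 - 1e-4)

  if (K == 1) {
    Q <- matrix(1, n, 1, dimnames = list(ids, "anc1"))
    P <- matrix(pobs, 1, L)
    ll <- admixture_loglik(d, Q, P)
    return(structure(list(Q = Q, P = P, loglik = ll, K = 1L, n_iter = 0L,
                          converged = TRUE, loglik_trace = ll),
                     class = "admixture_fit"))
  }

  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(seed + init)
    g0 <- matrix(rgamma(n * K, shape = 1), n, K)
    Q0 <- g0 / rowSums(g0)
    P0 <- matrix(rep(pobs, each = K), K, L) +
      matrix(runif(K * L, -0.1, 0.1), K, L)
    P0 <- pmin(pmax(P0, 1e-3), 1 - 1e-3)
    fit <- admixture_em_cpp(d, Q0, P0, max_iter, tol, pmin_)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  Q <- best$Q
  dimnames(Q) <- list(ids, paste0("anc", seq_len(K)))
  structure(list(Q = Q, P = best$P, loglik = best$loglik, K = as.integer(K),
                 n_iter = best$n_iter, converged = best$converged,
                 loglik_trace = best$trace),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, loglik = %.2f, %d EM iterations (%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Evanno delta-K model selection over admixture fits
#'
#' `delta_K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / SD(L(K))`,
#' computed over replicate runs; defined only for interior K. The selected
#' `k_star` maximizes delta-K. K values whose run SD is zero are excluded
#' with a warning (delta-K undefined there).
#'
#' @param logliks runs x K matrix of log-likelihoods; column names (or
#'   `ks`) give the K values, which must be consecutive.
#' @param ks integer vector of K values, one per column.
#' @return list with `table` (data.frame: `K`, `mean_loglik`, `sd_loglik`,
#'   `delta_k`) and `k_star`.
#' @export
evanno_delta_k <- function(logliks, ks = NULL) {
  logliks <- as.matrix(logliks)
  if (is.null(ks)) ks <- as.integer(colnames(logliks))
  if (anyNA(ks)) stop("supply K values via column names or `ks`")
  if (length(ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  if (nrow(logliks) < 2) stop("need >= 2 runs per K")
  m <- colMeans(logliks)
  s <- apply(logliks, 2, sd)
  dk <- rep(NA_real_, length(ks))
  interior <- seq(2, length(ks) - 1)
  for (j in interior) {
    if (s[j] == 0) {
      warning("SD of loglik is zero at K = ", ks[j],
              "; delta-K undefined there and excluded")
      next
    }
    dk[j] <- abs(m[j + 1] - 2 * m[j] + m[j - 1]) / s[j]
  }
  tab <- data.frame(K = ks, mean_loglik = m, sd_loglik = s, delta_k = dk,
                    row.names = NULL)
  if (all(is.na(dk))) {
    warning("delta-K undefined for every interior K")
    return(list(table = tab, k_star = NA_integer_))
  }
  list(table = tab, k_star = ks[which.max(dk)])
}

#' Align replicate admixture runs and form a consensus Q
#'
#' Ancestry labels are arbitrary per run; each run's columns are permuted
#' to maximize agreement (minimum squared difference) with the first run
#' -- exhaustively over the K! permutations for K <= 6, greedily
#' otherwise -- and the consensus is the element-wise mean, re-normalized
#' to the simplex.
#'
#' @param Q_runs list of individuals x K matrices (same shape).
#' @return consensus Q matrix.
#' @export
align_runs <- function(Q_runs) {
  stopifnot(length(Q_runs) >= 1)
  ref <- as.matrix(Q_runs[[1]])
  K <- ncol(ref)
  for (Qr in Q_runs) {
    if (!all(dim(as.matrix(Qr)) == dim(ref))) stop("runs differ in shape")
  }
  if (length(Q_runs) == 1) return(ref)

  perm_cols <- function(Q) {
    if (K <= 6) {
      perms <- all_permutations(K)
      costs <- vapply(perms, function(p) sum((Q[, p, drop = FALSE] - ref)^2),
                      numeric(1))
      perms[[which.min(costs)]]
    } else {
      # greedy assignment on the column-pair cost matrix
      cost <- outer(seq_len(K), seq_len(K), Vectorize(function(a, b) {
        sum((Q[, a] - ref[, b])^2)
      }))
      p <- integer(K)
      free_a <- seq_len(K); free_b <- seq_len(K)
      while (length(free_a)) {
        sub <- cost[free_a, free_b, drop = FALSE]
        w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        p[free_b[w[2]]] <- free_a[w[1]]
        free_a <- free_a[-w[1]]; free_b <- free_b[-w[2]]
      }
      p
    }
  }
  aligned <- lapply(Q_runs, function(Qr) {
    Qr <- as.matrix(Qr)
    Qr[, perm_cols(Qr), drop = FALSE]
  })
  cons <- Reduce(`+`, aligned) / length(aligned)
  cons / rowSums(cons)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

#' Classify individuals by majority parentage
#'
#' An individual is assigned to an ancestry when its membership strictly
#' exceeds `threshold` (the ">50% parentage" rule); otherwise it gets the
#' alternative label. Memberships exactly at the threshold therefore fall
#' to the alternative class; their indices are flagged in the `boundary`
#' attribute.
#'
#' @param Q individuals x K membership matrix with column names.
#' @param ancestry column name of the focal ancestry (e.g. `"sativa"`).
#' @param threshold membership cutoff in (0, 1); default 0.5.
#' @param other label for the alternative class; defaults to the other
#'   column name when K = 2, `"other"` otherwise.
#' @return character vector of labels, one per row of `Q`, with attribute
#'   `boundary` (indices where membership equals `threshold` exactly).
#' @export
classify_by_parentage <- function(Q, ancestry, threshold = 0.5, other = NULL) {
  Q <- as.matrix(Q)
  if (!ancestry %in% colnames(Q)) stop("no column named '", ancestry, "' in Q")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (is.null(other)) {
    other <- if (ncol(Q) == 2) setdiff(colnames(Q), ancestry) else "other"
  }
  q <- Q[, ancestry]
  labels <- ifelse(q > threshold, ancestry, other)
  names(labels) <- rownames(Q)
  attr(labels, "boundary") <- which(q == threshold)
  labels
}

#' Run the admixture model over a K grid with replicate runs
#'
#' Convenience driver for model selection: fits `runs` replicates at each
#' K in `kmin:kmax` (each replicate a fresh multi-start EM with its own
#' derived seed), applies [evanno_delta_k()], and returns the aligned
#' consensus Q at the selected K.
#'
#' @inheritParams fit_admixture
#' @param kmin,kmax K grid bounds.
#' @param runs replicate runs per K (>= 2).
#' @param n_init EM restarts within each run.
#' @return list: `logliks` (runs x K matrix), `evanno`, `k_star`,
#'   `Q_consensus` (at `k_star`), `fits` (list of the `k_star` fits).
#' @export
admixture_scan <- function(G, kmin = 1, kmax = 5, runs = 5, seed = 1,
                           n_init = 2, tol = 1e-4, max_iter = 500) {
  ks <- kmin:kmax
  logliks <- matrix(NA_real_, runs, length(ks),
                    dimnames = list(NULL, ks))
  fits_by_k <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    fits <- lapply(seq_len(runs), function(r) {
      fit_admixture(G, ks[j], seed = seed + 1000 * ks[j] + 17 * r,
                    n_init = n_init, tol = tol, max_iter = max_iter)
    })
    logliks[, j] <- vapply(fits, function(f) f$loglik, numeric(1))
    fits_by_k[[j]] <- fits
  }
  ev <- evanno_delta_k(logliks, ks = ks)
  k_star <- ev$k_star
  Qcons <- NULL
  star_fits <- NULL
  if (!is.na(k_star)) {
    star_fits <- fits_by_k[[match(k_star, ks)]]
    Qcons <- align_runs(lapply(star_fits, function(f) f$Q))
    rownames(Qcons) <- rownames(star_fits[[1]]$Q)
  }
  list(logliks = logliks, evanno = ev$table, k_star = k_star,
       Q_consensus = Qcons, fits = star_fits)
}
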