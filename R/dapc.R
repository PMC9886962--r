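#' Discriminant analysis of principal components
#'
#' Centered dosages are reduced by PCA; K-means (k-means++ seeding, 10
#' restarts) is run on the PC scores for each candidate cluster number,
#' and the cluster number minimizing `BIC(K) = n ln(WSS/n) + K ln(n)` is
#' chosen. Linear discriminant axes between the chosen clusters are then
#' computed on a retained subset of leading PCs whose size is selected by
#' held-out assignment accuracy over stratified splits (smallest count
#' within ties), guarding against over-fitting the discriminant space.
#'
#' @param G a [genotype_matrix()] (missing cells are mean-imputed on the
#'   fly) or a plain numeric matrix.
#' @param max_k largest candidate cluster number (`1 <= max_k < n`).
#' @param seed RNG seed (k-means restarts and cross-validation splits).
#' @param cluster_var cumulative variance fraction retained by the PCs
#'   used for cluster discovery.
#' @param pc_grid candidate retained-PC counts for the discriminant step;
#'   default a coarse grid up to `n - 2`.
#' @param cv_reps,cv_holdout stratified cross-validation replicates and
#'   held-out fraction.
#' @return object of class `dapc_result`: `K`, `assignments`, `bic`
#'   (data.frame `K`, `bic`), `n_pcs`, `scores` (individuals x (K-1)
#'   discriminant scores; zero columns when K = 1), `cv` accuracy table.
#' @export
dapc <- function(G, max_k = 6, seed = 1, cluster_var = 0.9, pc_grid = NULL,
                 cv_reps = 10, cv_holdout = 0.2) {
  X <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  n <- nrow(X)
  if (max_k < 1 || max_k >= n) stop("need 1 <= max_k < n individuals")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pca <- prcomp(Xc, center = FALSE)
  keep <- pca$sdev > 1e-10
  scores_all <- pca$x[, keep, drop = FALSE]
  cum <- cumsum(pca$sdev[keep]^2) / sum(pca$sdev[keep]^2)
  d_cluster <- max(1, min(which(cum >= cluster_var)))
  S <- scores_all[, seq_len(d_cluster), drop = FALSE]

  set.seed(seed)
  bic <- numeric(max_k)
  assign_by_k <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    km <- kmeanspp(S, k, restarts = 10)
    wss <- km$tot.withinss
    bic[k] <- n * log(wss / n) + k * log(n)
    assign_by_k[[k]] <- km$cluster
  }
  K <- which.min(bic)
  cl <- factor(assign_by_k[[K]])

  if (K == 1) {
    res <- list(K = 1L, assignments = setNames(rep(1L, n), rownames(X)),
                bic = data.frame(K = seq_len(max_k), bic = bic),
                n_pcs = 0L, scores = matrix(0, n, 0), cv = NULL)
    class(res) <- "dapc_result"
    return(res)
  }

  if (is.null(pc_grid)) {
    pc_grid <- unique(pmin(c(2, 5, 10, 20, 40, 80), ncol(scores_all)))
    pc_grid <- pc_grid[pc_grid <= n - 2 & pc_grid >= 1]
  }
  cv <- data.frame(n_pcs = pc_grid, accuracy = NA_real_)
  for (gi in seq_along(pc_grid)) {
    p <- pc_grid[gi]
    acc <- numeric(cv_reps)
    for (r in seq_len(cv_reps)) {
      set.seed(seed + 100 * gi + r)
      hold <- unlist(lapply(split(seq_len(n), cl), function(ix) {
        nh <- max(1, round(length(ix) * cv_holdout))
        if (length(ix) - nh < 2) return(integer(0))
        sample(ix, nh)
      }))
      if (length(hold) == 0 || length(unique(cl[-hold])) < 2) {
        acc[r] <- NA
        next
      }
      fit <- tryCatch(
        MASS::lda(scores_all[-hold, seq_len(p), drop = FALSE],
                  grouping = droplevels(cl[-hold])),
        error = function(e) NULL)
      if (is.null(fit)) { acc[r] <- NA; next }
      pred <- predict(fit, scores_all[hold, seq_len(p), drop = FALSE])$class
      acc[r] <- mean(as.character(pred) == as.character(cl[hold]))
    }
    cv$accuracy[gi] <- mean(acc, na.rm = TRUE)
  }
  best_acc <- max(cv$accuracy, na.rm = TRUE)
  n_pcs <- min(cv$n_pcs[!is.na(cv$accuracy) & cv$accuracy >= best_acc - 1e-12])

  lda_fit <- MASS::lda(scores_all[, seq_len(n_pcs), drop = FALSE], grouping = cl)
  sc <- predict(lda_fit, scores_all[, seq_len(n_pcs), drop = FALSE])$x
  res <- list(K = as.integer(K),
              assignments = setNames(as.integer(cl), rownames(X)),
              bic = data.frame(K = seq_len(max_k), bic = bic),
              n_pcs = as.integer(n_pcs), scores = sc, cv = cv)
  class(res) <- "dapc_result"
  res
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("dapc_result: K = %d clusters (BIC-selected), %d retained PCs\n",
              x$K, x$n_pcs))
  invisible(x)
}

# K-means with k-means++ seeding and multiple restarts; relies on the
# caller having set the RNG state.
kmeanspp <- function(X, k, restarts = 10, iter_max = 50) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
      for (j in 2:k) {
        prob <- d2 / sum(d2)
        if (all(d2 == 0)) prob <- rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
        d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                           byrow = TRUE))^2))
      }
    }
    km <- suppressWarnings(
      kmeans(X, centers = centers, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}
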