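#' Two-dimensional ordination of a distance matrix
#'
#' Embeds a sample dissimilarity matrix in two dimensions by principal
#' coordinate analysis (double centering + eigendecomposition, no
#' negative-eigenvalue correction; the negative eigenvalue mass is reported
#' in the diagnostics), non-metric multidimensional scaling (Kruskal
#' stress-1, best of several random starts), t-SNE or UMAP. All methods are
#' deterministic given the distance matrix, the options and the seed.
#'
#' @param d Symmetric distance matrix (zero diagonal, finite), n >= 4.
#' @param method `"pcoa"`, `"nmds"`, `"tsne"` or `"umap"`.
#' @param seed Integer seed (stochastic methods and NMDS restarts).
#' @param nmds_restarts Random starts for NMDS (default 20).
#' @param nmds_max_iter Maximum NMDS iterations per start (default 200).
#' @param tsne_perplexity t-SNE perplexity; default `min(30, floor((n-1)/3))`,
#'   shrunk (with a warning) when infeasible.
#' @param umap_n_neighbors,umap_min_dist UMAP graph size (default 15,
#'   shrunk when infeasible) and minimum embedding distance (default 0.1).
#'
#' @return An `embedding`: n x 2 coordinate matrix (rownames = sample ids)
#'   with attributes `method`, `seed` and `diagnostics` (NMDS stress, PCoA
#'   eigenvalues and relative negative eigenvalue mass).
#' @export
ordinate <- function(d, method = c("pcoa", "nmds", "tsne", "umap"),
                     seed = 1L,
                     nmds_restarts = 20L, nmds_max_iter = 200L,
                     tsne_perplexity = NULL,
                     umap_n_neighbors = 15L, umap_min_dist = 0.1) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 samples to ordinate")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (is.null(rownames(d))) rownames(d) <- sprintf("S%03d", seq_len(n))
  ids <- rownames(d)
  diagnostics <- list()

  if (method == "pcoa") {
    G <- -0.5 * .gower_center(d^2)
    eig <- eigen(G, symmetric = TRUE)
    ev <- eig$values
    diagnostics$eigenvalues <- ev
    diagnostics$negative_eigenvalue_mass <-
      sum(abs(ev[ev < 0])) / max(sum(abs(ev)), .Machine$double.eps)
    coords <- matrix(0, n, 2)
    pos <- which(ev > max(ev[1], 0) * 1e-12)
    for (k in seq_len(min(2L, length(pos)))) {
      coords[, k] <- eig$vectors[, pos[k]] * sqrt(ev[pos[k]])
    }
  } else if (method == "nmds") {
    set.seed(as.integer(seed))
    fit <- vegan::metaMDS(stats::as.dist(d), k = 2, trymax = nmds_restarts,
                          maxit = nmds_max_iter, trace = 0,
                          autotransform = FALSE, wascores = FALSE,
                          expand = FALSE)
    coords <- fit$points[, 1:2, drop = FALSE]
    diagnostics$stress <- fit$stress
    diagnostics$converged <- fit$converged
  } else if (method == "tsne") {
    maxp <- floor((n - 1) / 3)
    perp <- tsne_perplexity %||% min(30, maxp)
    if (perp > maxp) {
      warning("perplexity ", perp, " infeasible for n = ", n,
              "; shrunk to ", maxp)
      perp <- maxp
    }
    if (perp < 1) stop("too few samples for t-SNE")
    set.seed(as.integer(seed))
    fit <- Rtsne::Rtsne(d, is_distance = TRUE, dims = 2, perplexity = perp,
                        theta = 0, pca = FALSE, max_iter = 500,
                        check_duplicates = FALSE, verbose = FALSE)
    coords <- fit$Y
    diagnostics$perplexity <- perp
  } else {
    nb <- umap_n_neighbors
    if (nb >= n) {
      warning("n_neighbors ", nb, " infeasible for n = ", n,
              "; shrunk to ", n - 1L)
      nb <- n - 1L
    }
    set.seed(as.integer(seed))
    coords <- uwot::umap(stats::as.dist(d), n_components = 2,
                         n_neighbors = nb, min_dist = umap_min_dist,
                         n_threads = 1, n_sgd_threads = 1, verbose = FALSE)
    diagnostics$n_neighbors <- nb
  }
  rownames(coords) <- ids
  colnames(coords) <- c("axis1", "axis2")
  structure(coords, method = method, seed = seed, diagnostics = diagnostics,
            class = c("embedding", "matrix", "array"))
}

# Gower double centering of a (squared-distance) matrix
.gower_center <- function(A) {
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Euclidean distances between samples on an ordination embedding
#'
#' By default each axis is z-score standardized first, removing the
#' arbitrary global scale differences between ordination methods (PERMANOVA
#' on the result is scale-invariant either way, but machine-learning
#' feature ranges are not). Axes with zero spread are left as-is.
#'
#' @param emb An `embedding` from [ordinate()] (any n x 2 matrix works).
#' @param standardize Standardize axes before computing distances
#'   (default `TRUE`).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
embedding_distance <- function(emb, standardize = TRUE) {
  coords <- unclass(emb)
  if (any(!is.finite(coords))) stop("embedding contains non-finite coordinates")
  if (standardize) coords <- standardize_embedding(coords)
  d <- as.matrix(stats::dist(coords))
  attr(d, "index") <- paste0("embedding_", attr(emb, "method") %||% "euclidean")
  d
}

#' @rdname embedding_distance
#' @export
standardize_embedding <- function(emb) {
  coords <- unclass(emb)
  for (k in seq_len(ncol(coords))) {
    s <- stats::sd(coords[, k])
    if (is.finite(s) && s > 0)
      coords[, k] <- (coords[, k] - mean(coords[, k])) / s
  }
  coords
}
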