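#' Taxon-taxon association matrix for interaction-adjusted indices
#'
#' Builds the pairwise taxon similarity matrix used by the
#' interaction-adjusted dissimilarities. The abundance kind is the Spearman
#' rank correlation of taxa across samples rescaled to \[0, 1\] via
#' (rho + 1) / 2; the phylogenetic kind is one minus the cophenetic
#' distance scaled by its maximum. Both are symmetric with unit diagonal.
#'
#' @param mat Samples x taxa matrix (abundance kind; >= 3 samples).
#' @param kind `"abundance"` (TINA) or `"phylogenetic"` (PINA).
#' @param tree Phylogeny covering all taxa (phylogenetic kind).
#' @return Taxon x taxon similarity matrix in \[0, 1\].
#' @export
taxon_association <- function(mat = NULL, kind = c("abundance", "phylogenetic"),
                              tree = NULL) {
  kind <- match.arg(kind)
  if (kind == "abundance") {
    stopifnot(is.matrix(mat))
    if (nrow(mat) < 3) stop("abundance associations need >= 3 samples")
    rho <- suppressWarnings(stats::cor(mat, method = "spearman"))
    a <- (rho + 1) / 2
    if (any(is.na(a))) {
      warning("constant taxon profile(s): association set to 0.5")
      a[is.na(a)] <- 0.5
    }
    diag(a) <- 1
    a
  } else {
    if (is.null(tree)) stop("phylogenetic associations require a tree")
    coph <- stats::cophenetic(tree)
    a <- 1 - coph / max(coph)
    taxa <- if (!is.null(mat)) colnames(mat) else tree$tip.label
    a[taxa, taxa]
  }
}

#' Beta-diversity indices
#'
#' The sixteen pairwise sample dissimilarities benchmarked by the pipeline,
#' behind one dispatch interface. Classical ecological indices go through
#' [vegan::vegdist()]; correlation distances are 1 minus the Pearson or
#' Spearman correlation between sample profiles; `rf_proximity` is 1 minus
#' the proximity of an unsupervised random forest (samples never see any
#' outcome label, avoiding leakage into downstream testing); `tina_w` and
#' `pina_w` are abundance-weighted interaction-adjusted dissimilarities
#' over a taxon association matrix; and the UniFrac family (weighted,
#' generalized with alpha = 0.5, variance-adjusted weighted) operates on
#' per-sample relative abundances over the branches of the taxon phylogeny.
#'
#' UniFrac, TINA/PINA and the nonnegative ecological indices refuse
#' signed input (e.g. clr output); `chao` requires raw integer counts. Use
#' [combo_compatible()] to query valid (transform, index) pairs.
#'
#' @param mat Samples x features matrix (transformed counts).
#' @param index One of [beta_indices()].
#' @param tree Phylogeny (UniFrac family, and `pina_w` when `association`
#'   is not supplied).
#' @param association Optional precomputed taxon association matrix for
#'   `tina_w`/`pina_w`.
#' @param gunifrac_alpha Abundance weighting exponent for generalized
#'   UniFrac (default 0.5; `g_unifrac_05` keeps it at 0.5, alpha = 1
#'   recovers weighted UniFrac).
#' @param rf_trees Trees for the unsupervised random forest (default 500).
#' @param seed Integer seed (random forest).
#' @return Symmetric nonnegative matrix with zero diagonal and attribute
#'   `index`.
#' @export
beta_distance <- function(mat, index, tree = NULL, association = NULL,
                          gunifrac_alpha = 0.5, rf_trees = 500L, seed = NULL) {
  index <- match.arg(index, beta_indices())
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%03d", seq_len(nrow(mat)))
  if (any(!is.finite(mat))) stop("input matrix contains non-finite values")
  nonneg <- c("bray", "canberra", "kulczynski", "horn", "chao",
              "tina_w", "pina_w", "w_unifrac", "g_unifrac_05", "vaw_unifrac")
  if (index %in% nonneg && any(mat < 0))
    stop("index `", index, "` requires nonnegative input")
  d <- switch(index,
    euclidean = as.matrix(stats::dist(mat)),
    bray = as.matrix(vegan::vegdist(mat, method = "bray")),
    canberra = as.matrix(vegan::vegdist(mat, method = "canberra")),
    kulczynski = as.matrix(vegan::vegdist(mat, method = "kulczynski")),
    horn = as.matrix(vegan::vegdist(mat, method = "horn")),
    gower = as.matrix(vegan::vegdist(mat, method = "gower")),
    alt_gower = as.matrix(vegan::vegdist(mat, method = "altGower")),
    chao = {
      if (any(mat != round(mat)))
        stop("chao requires raw integer counts (use an integer-preserving transform)")
      as.matrix(vegan::vegdist(mat, method = "chao"))
    },
    pearson = .d_cor(mat, "pearson"),
    spearman = .d_cor(mat, "spearman"),
    rf_proximity = .d_rf(mat, rf_trees, seed),
    tina_w = .d_iaw(mat, association %||% taxon_association(mat, "abundance")),
    pina_w = .d_iaw(mat, association %||%
                      taxon_association(mat, "phylogenetic", tree = tree)),
    w_unifrac = .d_unifrac(mat, tree, "weighted"),
    g_unifrac_05 = .d_unifrac(mat, tree, "generalized", alpha = gunifrac_alpha),
    vaw_unifrac = .d_unifrac(mat, tree, "vaw")
  )
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0 & d > -1e-12] <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  attr(d, "index") <- index
  d
}

#' @rdname beta_distance
#' @export
beta_indices <- function() {
  c("euclidean", "bray", "canberra", "kulczynski", "horn", "gower",
    "alt_gower", "chao", "pearson", "spearman", "rf_proximity",
    "tina_w", "pina_w", "w_unifrac", "g_unifrac_05", "vaw_unifrac")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.d_cor <- function(mat, method) {
  r <- suppressWarnings(stats::cor(t(mat), method = method))
  if (any(is.na(r)))
    stop("constant sample profile(s): correlation distance undefined")
  1 - r
}

.d_rf <- function(mat, ntree, seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = as.data.frame(mat), y = NULL,
                                   ntree = ntree, proximity = TRUE)
  1 - rf$proximity
}

# interaction-adjusted weighted dissimilarity:
# s(A,B) = p_A' S p_B / sqrt((p_A' S p_A)(p_B' S p_B)), d = 1 - s
.d_iaw <- function(mat, assoc) {
  tot <- rowSums(mat)
  if (any(tot <= 0)) stop("sample(s) with zero total abundance")
  p <- mat / tot
  S <- p %*% assoc %*% t(p)
  ss <- diag(S)
  if (any(ss <= 0)) stop("sample(s) with zero self-similarity")
  sim <- S / sqrt(outer(ss, ss))
  sim <- pmin(pmax(sim, 0), 1)
  1 - sim
}

# per-edge relative-abundance mass for every sample (samples x edges)
.edge_abundance <- function(tree, P) {
  miss <- setdiff(colnames(P), tree$tip.label)
  if (length(miss))
    stop("tree is missing taxa: ", paste(utils::head(miss, 5), collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  acc <- matrix(0, nrow(P), ntip + tree$Nnode)
  acc[, seq_len(ntip)] <- P[, tree$tip.label, drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    acc[, tree$edge[e, 1]] <- acc[, tree$edge[e, 1]] + acc[, tree$edge[e, 2]]
  }
  list(E = acc[, tree$edge[, 2], drop = FALSE], len = tree$edge.length)
}

.d_unifrac <- function(mat, tree, variant, alpha = 0.5) {
  if (is.null(tree)) stop("UniFrac requires a taxon phylogeny")
  tot <- rowSums(mat)
  if (any(tot <= 0)) stop("sample(s) with zero total abundance")
  P <- mat / tot
  ea <- .edge_abundance(tree, P)
  E <- ea$E; len <- ea$len
  n <- nrow(P)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- E[i, ]; b <- E[j, ]
      m <- a + b
      dif <- abs(a - b)
      val <- switch(variant,
        weighted = {
          den <- sum(len * m)
          if (den == 0) 0 else sum(len * dif) / den
        },
        generalized = {
          nz <- m > 0
          den <- sum(len[nz] * m[nz]^alpha)
          if (den == 0) 0 else sum(len[nz] * m[nz]^alpha * dif[nz] / m[nz]) / den
        },
        vaw = {
          ok <- m > 0 & m < 2
          w <- 1 / sqrt(m[ok] * (2 - m[ok]))
          den <- sum(len[ok] * m[ok] * w)
          if (den == 0) 0 else sum(len[ok] * dif[ok] * w) / den
        })
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Declare which (transform, index) pairs are valid
#'
#' Some transformations produce signed or non-taxon feature spaces that
#' several indices cannot consume: log-ratio style outputs (clr, rclr, vst,
#' tmm, tmmwsp) are refused by the nonnegative ecological indices and by
#' the relative-abundance based UniFrac/TINA/PINA family; the chao index
#' needs raw integer counts and is only paired with rarefaction; k-mer
#' features are not taxa, so tree- and association-based indices and chao
#' do not apply.
#'
#' @param transform Transform name (see [transform_methods()]).
#' @param index Index name (see [beta_indices()]).
#' @return List with `ok` (logical) and `reason` (character, `NA` if ok).
#' @export
combo_compatible <- function(transform, index) {
  signed <- c("clr", "rclr", "vst", "tmm", "tmmwsp")
  nonneg_idx <- c("bray", "canberra", "kulczynski", "horn", "chao",
                  "tina_w", "pina_w", "w_unifrac", "g_unifrac_05",
                  "vaw_unifrac")
  taxa_idx <- c("chao", "tina_w", "pina_w", "w_unifrac", "g_unifrac_05",
                "vaw_unifrac")
  if (transform %in% signed && index %in% nonneg_idx)
    return(list(ok = FALSE, reason = paste0("index `", index,
      "` requires nonnegative input but `", transform, "` is signed")))
  if (index == "chao" && transform != "rarefy")
    return(list(ok = FALSE,
                reason = "chao requires integer counts (rarefy only)"))
  if (transform == "kmer" && index %in% taxa_idx)
    return(list(ok = FALSE,
                reason = "k-mer features are not taxa"))
  list(ok = TRUE, reason = NA_character_)
}
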