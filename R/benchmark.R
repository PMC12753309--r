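#' PERMANOVA pseudo-F from a distance matrix
#'
#' Direct implementation of the distance-based multivariate ANOVA
#' partition: the squared distances are Gower-centered into
#' G = -(1/2) J d^2 J and the pseudo-F is
#' (SS_model / df_model) / (SS_residual / df_residual), where the model
#' sum of squares is the trace of the projection of G onto the design. A
#' categorical variable with a levels uses df_model = a - 1; a continuous
#' variable is fit as a single linear term (df_model = 1). Significance is
#' by free permutation of the samples:
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param d Symmetric distance matrix.
#' @param variable Factor/character group labels (each level needs >= 2
#'   samples) or a numeric vector.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `F`, `p`, `df_model`, `df_residual`, `r2`.
#' @export
permanova_f <- function(d, variable, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 samples")
  if (length(variable) != n) stop("variable length must match the matrix")
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  categorical <- is.factor(variable) || is.character(variable) ||
    is.logical(variable)
  D2 <- d^2
  if (categorical) {
    g <- as.factor(as.character(variable))
    tab <- table(g)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L))
      stop("group(s) with a single sample: ",
           paste(names(tab)[tab < 2L], collapse = ", "))
    gi <- as.integer(g)
    sstot <- sum(D2) / (2 * n)
    dfm <- length(tab) - 1L
    dfr <- n - length(tab)
    fstat <- function(gi) {
      ssw <- 0
      for (k in unique(gi)) {
        idx <- gi == k
        ssw <- ssw + sum(D2[idx, idx]) / (2 * sum(idx))
      }
      ((sstot - ssw) / dfm) / (ssw / dfr)
    }
    F_obs <- fstat(gi)
    set.seed(as.integer(seed))
    F_perm <- vapply(seq_len(n_perm), function(b) fstat(gi[sample.int(n)]),
                     numeric(1))
    ssm <- sstot - sum(vapply(unique(gi), function(k) {
      idx <- gi == k; sum(D2[idx, idx]) / (2 * sum(idx))
    }, numeric(1)))
  } else {
    if (!is.numeric(variable) || any(!is.finite(variable)))
      stop("continuous variable must be finite numeric")
    if (stats::sd(variable) == 0) stop("continuous variable is constant")
    G <- -0.5 * .gower_center(D2)
    sstot <- sum(diag(G))
    dfm <- 1L
    dfr <- n - 2L
    fstat <- function(x) {
      xc <- x - mean(x)
      ssm <- drop(crossprod(xc, G %*% xc)) / sum(xc^2)
      (ssm / dfm) / ((sstot - ssm) / dfr)
    }
    F_obs <- fstat(variable)
    set.seed(as.integer(seed))
    F_perm <- vapply(seq_len(n_perm),
                     function(b) fstat(variable[sample.int(n)]), numeric(1))
    xc <- variable - mean(variable)
    ssm <- drop(crossprod(xc, G %*% xc)) / sum(xc^2)
  }
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  list(F = F_obs, p = p, df_model = dfm, df_residual = dfr,
       r2 = ssm / sstot)
}

#' Betadispersion F-statistic
#'
#' Multivariate homogeneity of group dispersions: samples are embedded by
#' principal coordinates (real and imaginary parts tracked), each sample's
#' distance to its group spatial centroid is computed (squared imaginary
#' contributions subtracted), and the one-way ANOVA F on those distances is
#' returned. Delegates to [vegan::betadisper()] with `type = "centroid"`.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels (>= 2 groups, each >= 2 samples).
#' @return The ANOVA F statistic (0, with a warning, when all centroid
#'   distances are zero).
#' @export
betadisper_f <- function(d, groups) {
  g <- as.factor(as.character(groups))
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("each group needs >= 2 samples")
  mod <- vegan::betadisper(stats::as.dist(as.matrix(d)), g, type = "centroid")
  if (all(mod$distances < 1e-12)) {
    warning("all centroid distances are zero; F set to 0")
    return(0)
  }
  an <- stats::anova(mod)
  f <- an[["F value"]][1]
  if (!is.finite(f)) {
    warning("degenerate dispersion ANOVA; F set to 0")
    f <- 0
  }
  f
}

#' Run the combination benchmark grid
#'
#' Scores every valid (transform, index, ordination) combination on every
#' dataset pair by PERMANOVA pseudo-F: at the distance level
#' (`ordination == "none"`) and at the embedding level (Euclidean distances
#' on the 2-D ordination coordinates), for both the modern and the
#' degraded ("ancient") version of each dataset. For degraded datasets the
#' betadispersion F across effect levels is recorded as well. Incompatible
#' combinations are skipped and logged in the result.
#'
#' @param pairs List of dataset pairs; each element is
#'   `list(modern = <community_dataset>, ancient = <community_dataset>)`
#'   (ancient carrying its `$degradation` plan).
#' @param combos Data frame with columns `transform`, `index`, `ordination`
#'   (`"none"` for distance-level scoring). See [default_combos()].
#' @param n_perm Permutations per PERMANOVA (default 199).
#' @param seed Integer seed.
#' @param nmds_restarts,rf_trees Passed to the respective steps (reduced
#'   defaults keep grid runs tractable).
#' @return List with `records` (one row per scored combination),
#'   `ranks` (combos ordered by median F within dna_status, ties broken by
#'   mean F then combo name) and `skipped` (logged incompatibilities).
#' @export
run_benchmark_grid <- function(pairs, combos, n_perm = 199L, seed = 1L,
                               nmds_restarts = 5L, rf_trees = 200L) {
  stopifnot(is.data.frame(combos),
            all(c("transform", "index", "ordination") %in% names(combos)))
  if (!nrow(combos)) stop("empty combination list")
  if (!is.null(pairs$modern)) pairs <- list(pairs)
  records <- list()
  skipped <- list()
  for (di in seq_along(pairs)) {
    pair <- pairs[[di]]
    ds_id <- names(pairs)[di] %||% paste0("dataset", di)
    if (ds_id == "") ds_id <- paste0("dataset", di)
    for (status in c("modern", "ancient")) {
      ds <- pair[[status]]
      target <- if (ds$mode == "cluster") ds$metadata$cluster else
        ds$metadata$gradient
      anns <- ds$annotations %||% pair$modern$annotations
      tcache <- list()
      dcache <- list()
      for (ci in seq_len(nrow(combos))) {
        tr <- combos$transform[ci]; ix <- combos$index[ci]
        or <- combos$ordination[ci]
        comp <- combo_compatible(tr, ix)
        if (!comp$ok) {
          skipped[[length(skipped) + 1]] <- data.frame(
            dataset = ds_id, dna_status = status, transform = tr, index = ix,
            ordination = or, reason = comp$reason)
          next
        }
        if (is.null(tcache[[tr]]))
          tcache[[tr]] <- transform_counts(
            ds$counts, tr, sequences = anns$sequences, seed = seed)
        key <- paste(tr, ix)
        if (is.null(dcache[[key]]))
          dcache[[key]] <- beta_distance(
            tcache[[tr]], ix, tree = anns$tree, rf_trees = rf_trees,
            seed = seed)
        dmat <- dcache[[key]]
        if (or != "none") {
          emb <- ordinate(dmat, or, seed = seed,
                          nmds_restarts = nmds_restarts)
          dmat <- embedding_distance(emb)
        }
        res <- permanova_f(dmat, target, n_perm = n_perm, seed = seed)
        bdf <- NA_real_
        if (status == "ancient" && !is.null(ds$degradation)) {
          lvl <- ds$degradation$assignments$level[
            match(rownames(ds$counts), ds$degradation$assignments$sample_id)]
          bdf <- tryCatch(suppressWarnings(betadisper_f(dmat, factor(lvl))),
                          error = function(e) NA_real_)
        }
        records[[length(records) + 1]] <- data.frame(
          dataset = ds_id, dna_status = status,
          target_kind = ds$mode, transform = tr, index = ix,
          ordination = or, pseudo_F = res$F, p_value = res$p,
          betadisper_F = bdf, seed = seed)
      }
    }
  }
  records <- do.call(rbind, records)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  list(records = records, ranks = rank_combos(records), skipped = skipped)
}

#' @rdname run_benchmark_grid
#' @param records A benchmark `records` data frame.
#' @export
rank_combos <- function(records) {
  records$combo <- paste(records$transform, records$index,
                         records$ordination, sep = "+")
  out <- list()
  for (status in unique(records$dna_status)) {
    sub <- records[records$dna_status == status, ]
    agg_med <- stats::aggregate(pseudo_F ~ combo, sub, stats::median)
    agg_mean <- stats::aggregate(pseudo_F ~ combo, sub, mean)
    tab <- data.frame(dna_status = status, combo = agg_med$combo,
                      median_F = agg_med$pseudo_F,
                      mean_F = agg_mean$pseudo_F[match(agg_med$combo,
                                                       agg_mean$combo)])
    tab <- tab[order(-tab$median_F, -tab$mean_F, tab$combo,
                     method = "radix"), ]
    tab$rank <- seq_len(nrow(tab))
    out[[status]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Default combination list
#'
#' All pairings of the requested transforms, indices and ordinations
#' (plus, optionally, `"none"` for distance-level scoring); incompatible
#' pairs are kept in the table and skipped at run time by
#' [run_benchmark_grid()].
#'
#' @param transforms,indices,ordinations Character vectors of method names.
#' @param include_distance_level Include `ordination = "none"` rows.
#' @return Data frame with columns `transform`, `index`, `ordination`.
#' @export
default_combos <- function(transforms = transform_methods(),
                           indices = beta_indices(),
                           ordinations = c("pcoa", "nmds", "tsne", "umap"),
                           include_distance_level = TRUE) {
  ords <- if (include_distance_level) c("none", ordinations) else ordinations
  expand.grid(transform = transforms, index = indices, ordination = ords,
              stringsAsFactors = FALSE)
}
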