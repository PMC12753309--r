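#' Min-max normalize an ecological gradient to \[0, 1\]
#'
#' Keeps regression RMSE comparable across datasets whose gradients are on
#' different scales; the result is invariant to affine transformations of
#' the input.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Numeric vector with minimum 0 and maximum 1.
#' @export
normalize_gradient <- function(values) {
  if (any(!is.finite(values))) stop("gradient values must be finite")
  r <- range(values)
  if (r[1] == r[2]) stop("gradient is constant; cannot normalize")
  (values - r[1]) / (r[2] - r[1])
}

.is_classification <- function(target)
  is.factor(target) || is.character(target) || is.logical(target)

.metric <- function(pred, obs) {
  if (.is_classification(obs)) mean(as.character(pred) == as.character(obs))
  else sqrt(mean((as.numeric(pred) - obs)^2))
}

.fit_predict <- function(algorithm, xtr, ytr, xte, k = 5L, rf_trees = 500L) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  if (algorithm == "knn") {
    k <- min(k, nrow(xtr))
    if (.is_classification(ytr)) {
      as.character(class::knn(xtr, xte, factor(ytr), k = k))
    } else {
      stats::predict(caret::knnreg(xtr, ytr, k = k), xte)
    }
  } else {
    y <- if (.is_classification(ytr)) factor(ytr) else ytr
    fit <- randomForest::randomForest(x = xtr, y = y, ntree = rf_trees)
    pred <- stats::predict(fit, xte)
    if (.is_classification(ytr)) as.character(pred) else as.numeric(pred)
  }
}

# stratified (classification) or plain fold assignment
.make_folds <- function(target, k) {
  n <- length(target)
  folds <- integer(n)
  if (.is_classification(target)) {
    for (cl in unique(as.character(target))) {
      idx <- which(as.character(target) == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

# repeated k-fold CV tuning of the KNN neighbourhood size; ties -> smallest k
.tune_knn <- function(x, y, k_grid, folds, repeats, rf_trees) {
  classification <- .is_classification(y)
  k_grid <- k_grid[k_grid < length(y)]
  if (!length(k_grid)) k_grid <- 1L
  score <- matrix(NA_real_, repeats * folds, length(k_grid))
  row <- 0L
  for (r in seq_len(repeats)) {
    fid <- .make_folds(y, folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      te <- fid == f
      if (!any(te) || all(te)) next
      if (classification &&
          length(unique(as.character(y[!te]))) < length(unique(as.character(y))))
        next
      for (ki in seq_along(k_grid)) {
        pred <- .fit_predict("knn", x[!te, , drop = FALSE], y[!te],
                             x[te, , drop = FALSE], k = k_grid[ki])
        score[row, ki] <- .metric(pred, y[te])
      }
    }
  }
  avg <- colMeans(score, na.rm = TRUE)
  best <- if (classification) which.max(avg) else which.min(avg)
  k_grid[best]
}

#' Cross-validated model evaluation on one feature matrix
#'
#' Implements the evaluation protocol used throughout the benchmark: a
#' stratified (classification) or plain (regression) 60-40 train-test
#' split; the KNN neighbourhood size is tuned by repeated 10-fold
#' cross-validation inside the training partition (random forests are run
#' untuned at `rf_trees` trees); the final model is fit on the full
#' training partition and the reported metric (accuracy, or RMSE for
#' regression) is computed on the held-out 40%. Fully deterministic under
#' the seed.
#'
#' @param features Samples x features numeric matrix.
#' @param target Factor/character labels (classification) or numeric vector
#'   (regression; normalize with [normalize_gradient()] first for
#'   comparable RMSE).
#' @param algorithm `"knn"` or `"rf"`.
#' @param train_fraction Training fraction (default 0.6).
#' @param cv_folds,cv_repeats Folds and repeats of the tuning CV
#'   (defaults 10 and 10).
#' @param knn_k_grid Candidate neighbourhood sizes (default odd 1..11).
#' @param rf_trees Random forest size (default 500).
#' @param seed Integer seed.
#' @return List with `metric`, `metric_name`, `best_k` (KNN), `n_train`,
#'   `n_test`.
#' @export
cross_validate <- function(features, target, algorithm = c("knn", "rf"),
                           train_fraction = 0.6, cv_folds = 10L,
                           cv_repeats = 10L,
                           knn_k_grid = c(1L, 3L, 5L, 7L, 9L, 11L),
                           rf_trees = 500L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(target) == n)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  classification <- .is_classification(target)
  if (classification && length(unique(as.character(target))) < 2L)
    stop("classification needs at least 2 classes")
  set.seed(as.integer(seed))
  if (classification) {
    tr <- integer(0)
    for (cl in unique(as.character(target))) {
      idx <- which(as.character(target) == cl)
      if (length(idx) < 2L)
        stop("class `", cl, "` has fewer than 2 samples; cannot stratify")
      tr <- c(tr, resample(idx, max(1L, round(train_fraction * length(idx)))))
    }
  } else {
    tr <- resample(seq_len(n), max(2L, round(train_fraction * n)))
  }
  te <- setdiff(seq_len(n), tr)
  if (!length(te)) stop("empty test partition")
  xtr <- features[tr, , drop = FALSE]; ytr <- target[tr]
  xte <- features[te, , drop = FALSE]; yte <- target[te]
  best_k <- NA_integer_
  if (algorithm == "knn") {
    folds <- min(cv_folds, length(tr))
    best_k <- .tune_knn(xtr, ytr, knn_k_grid, folds, cv_repeats, rf_trees)
  }
  pred <- .fit_predict(algorithm, xtr, ytr, xte, k = best_k,
                       rf_trees = rf_trees)
  list(metric = .metric(pred, yte),
       metric_name = if (classification) "accuracy" else "rmse",
       best_k = best_k, n_train = length(tr), n_test = length(te))
}

#' Evaluate a transfer function: train on modern, predict ancient
#'
#' Builds the feature space for one method combination over the modern and
#' degraded ("ancient") versions of a dataset, cross-validates the model
#' within each domain, and evaluates the transfer function: a model
#' calibrated only on the modern samples, applied to the ancient samples,
#' scored overall and per ancient-DNA effect level.
#'
#' Composition features are the transformed counts; embedding features are
#' the (per-axis standardized) coordinates of one joint ordination of the
#' modern and ancient samples together — NMDS and PCoA have no
#' out-of-sample projection, so a joint embedding is the only construction
#' that treats the four ordinations uniformly. Transforms with fitted
#' parameters are likewise fit on modern + ancient jointly (set
#' `joint_fit = FALSE` for a modern-only fit of composition features).
#'
#' @param modern,ancient `community_dataset`s sharing taxa and metadata
#'   schema; `ancient` carries its `$degradation` plan.
#' @param combo List with `feature_space` (`"composition"` or
#'   `"embedding"`), `transform`, and for embeddings `index` and
#'   `ordination`.
#' @param algorithm `"knn"` or `"rf"`.
#' @param joint_fit Fit parametrized transforms on both domains jointly
#'   (default `TRUE`).
#' @param nmds_restarts Restarts for NMDS embeddings (default 5).
#' @inheritParams cross_validate
#' @return Data frame with one row per effect level (plus `"all"`):
#'   `feature_space`, `transform`, `index`, `ordination`, `algorithm`,
#'   `effect_level`, `n`, `cv_modern`, `cv_ancient`, `transfer`,
#'   `metric_name`, `seed`.
#' @export
transfer_evaluate <- function(modern, ancient, combo,
                              algorithm = c("knn", "rf"),
                              train_fraction = 0.6, cv_folds = 10L,
                              cv_repeats = 10L,
                              knn_k_grid = c(1L, 3L, 5L, 7L, 9L, 11L),
                              rf_trees = 500L, seed = 1L,
                              joint_fit = TRUE, nmds_restarts = 5L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(modern, "community_dataset"),
            inherits(ancient, "community_dataset"))
  if (!identical(colnames(modern$counts), colnames(ancient$counts)))
    stop("modern and ancient datasets must share taxa")
  fs <- match.arg(combo$feature_space, c("composition", "embedding"))
  comp <- combo_compatible(combo$transform, combo$index %||% "euclidean")
  if (fs == "embedding" && !comp$ok) stop("incompatible combo: ", comp$reason)
  anns <- modern$annotations %||% ancient$annotations
  nm <- nrow(modern$counts); na <- nrow(ancient$counts)
  joint <- rbind(modern$counts, ancient$counts)
  rownames(joint) <- c(paste0("mod|", rownames(modern$counts)),
                       paste0("anc|", rownames(ancient$counts)))
  if (fs == "composition" && !joint_fit) {
    fm <- transform_counts(modern$counts, combo$transform,
                           sequences = anns$sequences, seed = seed)
    fa <- transform_counts(ancient$counts, combo$transform,
                           sequences = anns$sequences, seed = seed)
    feats <- rbind(fm, fa)
  } else {
    tmat <- transform_counts(joint, combo$transform,
                             sequences = anns$sequences, seed = seed)
    feats <- if (fs == "composition") tmat else {
      d <- beta_distance(tmat, combo$index, tree = anns$tree, seed = seed)
      standardize_embedding(ordinate(d, combo$ordination, seed = seed,
                                     nmds_restarts = nmds_restarts))
    }
  }
  fmod <- feats[seq_len(nm), , drop = FALSE]
  fanc <- feats[nm + seq_len(na), , drop = FALSE]
  if (modern$mode == "cluster") {
    ymod <- modern$metadata$cluster
    yanc <- ancient$metadata$cluster
  } else {
    yall <- normalize_gradient(c(modern$metadata$gradient,
                                 ancient$metadata$gradient))
    ymod <- yall[seq_len(nm)]
    yanc <- yall[nm + seq_len(na)]
  }
  cvm <- cross_validate(fmod, ymod, algorithm, train_fraction, cv_folds,
                        cv_repeats, knn_k_grid, rf_trees, seed = seed)
  cva <- cross_validate(fanc, yanc, algorithm, train_fraction, cv_folds,
                        cv_repeats, knn_k_grid, rf_trees, seed = seed)
  # transfer: calibrate on all modern samples, predict the ancient ones
  set.seed(as.integer(seed))
  best_k <- NA_integer_
  if (algorithm == "knn") {
    folds <- min(cv_folds, nm)
    best_k <- .tune_knn(fmod, ymod, knn_k_grid, folds, cv_repeats, rf_trees)
  }
  pred <- .fit_predict(algorithm, fmod, ymod, fanc, k = best_k,
                       rf_trees = rf_trees)
  lv <- if (!is.null(ancient$degradation)) {
    ancient$degradation$assignments$level[
      match(rownames(ancient$counts), ancient$degradation$assignments$sample_id)]
  } else rep(0, na)
  rows <- lapply(c("all", sort(unique(lv))), function(l) {
    idx <- if (identical(l, "all")) seq_len(na) else which(lv == l)
    data.frame(feature_space = fs, transform = combo$transform,
               index = combo$index %||% NA_character_,
               ordination = combo$ordination %||% NA_character_,
               algorithm = algorithm, effect_level = as.character(l),
               n = length(idx),
               cv_modern = cvm$metric, cv_ancient = cva$metric,
               transfer = .metric(pred[idx], yanc[idx]),
               metric_name = cvm$metric_name, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# compact letter display from a matrix/vector of significant pairs
.cld_letters <- function(groups, sig_pairs, alpha = 0.05) {
  sets <- list(groups)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[r, 1]; b <- sig_pairs[r, 2]
      new <- list()
      for (s in sets) {
        if (a %in% s && b %in% s)
          new <- c(new, list(setdiff(s, a)), list(setdiff(s, b)))
        else new <- c(new, list(s))
      }
      # keep only maximal sets
      keep <- rep(TRUE, length(new))
      for (i in seq_along(new)) for (j in seq_along(new)) {
        if (i != j && keep[i] && keep[j] && all(new[[i]] %in% new[[j]]) &&
            length(new[[i]]) < length(new[[j]]))
          keep[i] <- FALSE
      }
      sets <- unique(new[keep])
    }
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), 1))]
  out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
           collapse = "")
  }, character(1))
  out
}

#' Aggregate top transfer approaches and compare them by Tukey HSD
#'
#' Selects the `top_n` best method combinations within every
#' (feature space, algorithm) approach by median transfer metric, then at
#' each ancient-DNA effect level runs a one-way ANOVA across approaches on
#' the aggregated metrics followed by Tukey's Honest Significant
#' Difference, summarized as a compact letter display (approaches sharing
#' a letter are not significantly different at the 0.05 level).
#'
#' @param records Rows produced by [transfer_evaluate()] (per-level rows;
#'   `"all"` rows are ignored), ideally over several datasets.
#' @param top_n Combinations kept per approach (default 5).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `top` (selected combos and their median metric) and
#'   `comparison` (per effect level: approach, n, mean, median, letters).
#' @export
aggregate_transfer <- function(records, top_n = 5L, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  rec <- records[records$effect_level != "all", , drop = FALSE]
  if (!nrow(rec)) stop("no per-level transfer records")
  rec$combo <- paste(rec$transform, rec$index, rec$ordination, sep = "+")
  rec$approach <- paste(rec$feature_space, rec$algorithm, sep = "_")
  better_high <- rec$metric_name[1] == "accuracy"
  if (length(unique(rec$approach)) < 2L)
    stop("need at least 2 (feature space x algorithm) approaches")
  top <- list()
  for (ap in unique(rec$approach)) {
    sub <- rec[rec$approach == ap, ]
    med <- stats::aggregate(transfer ~ combo, sub, stats::median)
    med <- med[order(if (better_high) -med$transfer else med$transfer,
                     med$combo, method = "radix"), ]
    top[[ap]] <- data.frame(approach = ap,
                            combo = utils::head(med$combo, top_n),
                            median_metric = utils::head(med$transfer, top_n))
  }
  top <- do.call(rbind, c(top, make.row.names = FALSE))
  sel <- rec[paste(rec$approach, rec$combo) %in%
               paste(top$approach, top$combo), ]
  out <- list()
  for (l in sort(unique(sel$effect_level))) {
    sub <- sel[sel$effect_level == l, ]
    tab <- table(sub$approach)
    if (length(tab) < 2L || any(tab < 2L)) next
    fit <- stats::aov(transfer ~ approach, data = sub)
    tk <- stats::TukeyHSD(fit)$approach
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    sig <- pairs[tk[, "p adj"] < alpha, , drop = FALSE]
    means <- stats::aggregate(transfer ~ approach, sub, mean)
    ord <- order(if (better_high) -means$transfer else means$transfer)
    groups <- means$approach[ord]
    lets <- .cld_letters(groups, sig, alpha)
    out[[length(out) + 1]] <- data.frame(
      effect_level = l, approach = groups,
      n = as.integer(tab[groups]),
      mean = means$transfer[ord],
      median = vapply(groups, function(g)
        stats::median(sub$transfer[sub$approach == g]), numeric(1)),
      letters = lets, row.names = NULL)
  }
  list(top = top, comparison = do.call(rbind, out))
}
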