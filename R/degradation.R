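#' Assign ancient-DNA effect levels to samples
#'
#' Splits the samples evenly over the four effect levels 0, 0.25, 0.50 and
#' 0.75 (the target fractions of detected taxa turned into false
#' negatives). In cluster mode the split is balanced within every class so
#' each community type contributes equally to each level; in gradient mode
#' samples are assigned at random with respect to their gradient value.
#' Any remainder is distributed round-robin in the order (0, 0.25, 0.50,
#' 0.75).
#'
#' @param metadata A `community_dataset` or its metadata data.frame (must
#'   contain `sample_id` plus `cluster` for cluster mode).
#' @param mode `"cluster"` or `"gradient"`.
#' @param seed Integer seed.
#' @param noise_halfwidth Half-width of the uniform jitter later applied to
#'   the target dropout fraction by [degrade_counts()] (default 0.03).
#'
#' @return An object of class `degradation_plan`: list with `assignments`
#'   (data.frame `sample_id`, `level`), `noise_halfwidth`, `seed`, and
#'   empty slots `dropped`/`recipients`/`realized_fraction` filled in by
#'   [degrade_counts()].
#' @export
assign_effect_levels <- function(metadata, mode = c("cluster", "gradient"),
                                 seed = 1L, noise_halfwidth = 0.03) {
  mode <- match.arg(mode)
  if (inherits(metadata, "community_dataset")) metadata <- metadata$metadata
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  n <- nrow(metadata)
  if (n < 4L) stop("need at least 4 samples to assign four effect levels")
  if (noise_halfwidth < 0) stop("`noise_halfwidth` must be >= 0")
  levels <- c(0, 0.25, 0.50, 0.75)
  set.seed(as.integer(seed))
  lv <- numeric(n)
  if (mode == "cluster") {
    if (!"cluster" %in% names(metadata))
      stop("cluster mode requires a `cluster` column in the metadata")
    classes <- unique(metadata$cluster)
    small <- classes[table(factor(metadata$cluster, levels = classes)) < 4L]
    if (length(small))
      warning("class(es) with fewer than 4 samples (",
              paste(small, collapse = ", "),
              "); effect levels assigned best-effort")
    ptr <- 0L
    for (cl in classes) {
      idx <- which(metadata$cluster == cl)
      idx <- idx[sample.int(length(idx))]
      lv[idx] <- levels[(ptr + seq_along(idx) - 1L) %% 4L + 1L]
      ptr <- (ptr + length(idx)) %% 4L
    }
  } else {
    idx <- sample.int(n)
    lv[idx] <- levels[(seq_len(n) - 1L) %% 4L + 1L]
  }
  structure(list(
    assignments = data.frame(sample_id = metadata$sample_id, level = lv,
                             stringsAsFactors = FALSE),
    noise_halfwidth = noise_halfwidth,
    seed = as.integer(seed),
    dropped = NULL, recipients = NULL, realized_fraction = NULL
  ), class = "degradation_plan")
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Inject ancient-DNA dropout noise into a count matrix
#'
#' For every sample at effect level e > 0, a uniformly random subset of its
#' detected (nonzero) taxa of size `round((e + jitter) * n_detected)` is
#' set to zero (false negatives), with jitter uniform on
#' `[-noise_halfwidth, +noise_halfwidth]`. The reads removed from those
#' taxa are reallocated to a random nonempty subset of the sample's 10%
#' most abundant taxa (ranked before dropout), proportionally to their
#' pre-dropout abundances with largest-remainder integer rounding, so every
#' sample keeps exactly its original sequencing depth. Level-0 samples are
#' returned unchanged.
#'
#' @param dataset A `community_dataset` (or bare integer count matrix with
#'   dimnames).
#' @param plan A `degradation_plan` from [assign_effect_levels()] covering
#'   all samples.
#'
#' @return The degraded dataset (same class as the input); the realized
#'   plan (dropout sets, recipients, realized dropout fractions) is stored
#'   in `$degradation` (or attribute `"degradation"` for a bare matrix).
#' @export
degrade_counts <- function(dataset, plan) {
  stopifnot(inherits(plan, "degradation_plan"))
  is_ds <- inherits(dataset, "community_dataset")
  counts <- if (is_ds) dataset$counts else dataset
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (!all(rownames(counts) %in% plan$assignments$sample_id))
    stop("plan does not cover all samples")
  lv <- plan$assignments$level[match(rownames(counts),
                                     plan$assignments$sample_id)]
  hw <- plan$noise_halfwidth
  set.seed(plan$seed)
  dropped <- vector("list", nrow(counts))
  recip <- vector("list", nrow(counts))
  realized <- rep(NA_real_, nrow(counts))
  names(dropped) <- names(recip) <- names(realized) <- rownames(counts)

  for (i in seq_len(nrow(counts))) {
    e <- lv[i]
    if (e == 0) {
      dropped[[i]] <- integer(0); recip[[i]] <- integer(0); realized[i] <- 0
      next
    }
    x <- counts[i, ]
    det <- which(x > 0L)
    nd <- length(det)
    if (nd < 2L) {
      warning("sample ", rownames(counts)[i],
              " has fewer than 2 detected taxa; skipped")
      dropped[[i]] <- integer(0); recip[[i]] <- integer(0); realized[i] <- 0
      next
    }
    jit <- stats::runif(1, -hw, hw)
    frac <- min(max(e + jit, 1 / nd), (nd - 1) / nd)
    n_drop <- min(max(round(frac * nd), 1L), nd - 1L)
    m <- max(1L, floor(0.10 * nd))
    top <- det[order(-x[det], det)][seq_len(m)]
    # draw the dropout set, requiring at least one surviving top-decile taxon
    drop_set <- NULL
    for (try in 1:100) {
      cand <- resample(det, n_drop)
      if (length(setdiff(top, cand)) > 0L) { drop_set <- cand; break }
    }
    if (is.null(drop_set)) {
      # all draws covered the decile: keep the most abundant taxon alive
      drop_set <- setdiff(cand, top[1])
    }
    survivors <- setdiff(top, drop_set)
    rec <- resample(survivors, sample.int(length(survivors), 1L))
    removed <- sum(x[drop_set])
    if (removed > 0L) {
      w <- x[rec] / sum(x[rec])
      raw <- removed * w
      base <- floor(raw)
      rem <- removed - sum(base)
      if (rem > 0L) {
        ord <- order(-(raw - base), -x[rec], rec)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
      }
      x[rec] <- x[rec] + as.integer(base)
    }
    x[drop_set] <- 0L
    counts[i, ] <- x
    dropped[[i]] <- drop_set
    recip[[i]] <- rec
    realized[i] <- length(drop_set) / nd
  }
  plan$dropped <- dropped
  plan$recipients <- recip
  plan$realized_fraction <- realized
  if (is_ds) {
    dataset$counts <- counts
    dataset$degradation <- plan
    dataset
  } else {
    attr(counts, "degradation") <- plan
    counts
  }
}
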