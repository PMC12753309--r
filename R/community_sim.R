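#' Draw a per-run simulation parameter set
#'
#' Each simulated community uses a unique parameter set drawn from uniform
#' distributions, so that every run of the benchmark sees a different but
#' realistic community structure. The hierarchical generator is: per-taxon
#' baseline log-abundances are uniform on `baseline_logmean_range`; a drawn
#' fraction `de_prob` of taxa respond to the community structure (cluster
#' membership or gradient position) with fold changes drawn from
#' `de_factor_range`; per-sample library sizes are log-normal around
#' `library_size_mean` with coefficient of variation `library_size_cv`; and
#' counts are negative-binomial around the expected per-sample composition
#' with dispersion `dispersion` (variance = mu + dispersion * mu^2).
#'
#' @param seed Integer seed; the same seed always yields the same parameter
#'   set.
#' @param mode `"cluster"` (discrete community types) or `"path"`
#'   (continuous ecological gradient).
#' @param overrides Named list overriding any drawn or fixed field of the
#'   result (e.g. `list(n_samples = 50)`). Unknown names are an error.
#'
#' @return An object of class `sim_params`: a list with fields `n_samples`,
#'   `n_taxa`, `mode`, `n_clusters`, `library_size_mean`, `library_size_cv`,
#'   `baseline_logmean_range`, `de_prob`, `de_factor_range`, `dispersion`
#'   and `seed`, with the uniform bounds used for the draws attached as
#'   attribute `"bounds"`.
#' @export
draw_sim_params <- function(seed, mode = c("cluster", "path"),
                            overrides = list()) {
  mode <- match.arg(mode)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer")
  bounds <- list(
    library_size_mean = c(2e4, 5e4),
    library_size_cv   = c(0.1, 0.3),
    de_prob           = c(0.1, 0.4),
    dispersion        = c(0.05, 0.4)
  )
  set.seed(as.integer(seed))
  params <- list(
    n_samples  = 100L,
    n_taxa     = 400L,
    mode       = mode,
    n_clusters = 5L,
    library_size_mean = stats::runif(1, bounds$library_size_mean[1], bounds$library_size_mean[2]),
    library_size_cv   = stats::runif(1, bounds$library_size_cv[1], bounds$library_size_cv[2]),
    baseline_logmean_range = c(-2, 2),
    de_prob           = stats::runif(1, bounds$de_prob[1], bounds$de_prob[2]),
    de_factor_range   = c(2, 6),
    dispersion        = stats::runif(1, bounds$dispersion[1], bounds$dispersion[2]),
    seed = as.integer(seed)
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad))
      stop("unknown sim_params override(s): ", paste(bad, collapse = ", "))
    params[names(overrides)] <- overrides
  }
  for (f in c("baseline_logmean_range", "de_factor_range")) {
    r <- params[[f]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop("`", f, "` must be a finite interval with lower <= upper")
  }
  if (params$library_size_mean <= 0) stop("`library_size_mean` must be > 0")
  if (params$de_prob < 0 || params$de_prob > 1) stop("`de_prob` must be in [0, 1]")
  if (params$mode == "cluster" && params$n_clusters < 2L)
    stop("cluster mode needs `n_clusters` >= 2")
  attr(params, "bounds") <- bounds
  class(params) <- "sim_params"
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Community simulation parameters (", x$mode, " mode, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  %d samples x %d taxa", x$n_samples, x$n_taxa))
  if (x$mode == "cluster") cat(sprintf(", %d clusters", x$n_clusters))
  cat("\n")
  cat(sprintf("  library size ~ logN(mean %.0f, cv %.2f); de_prob %.2f; NB dispersion %.3f\n",
              x$library_size_mean, x$library_size_cv, x$de_prob, x$dispersion))
  invisible(x)
}

#' Simulate a community count matrix
#'
#' Generates an integer samples-by-taxa count matrix under the hierarchical
#' negative-binomial model described in [draw_sim_params()]. In cluster mode
#' samples are split into near-equal clusters (sizes differing by at most
#' one) and differentially abundant taxa change mean abundance between
#' clusters by the drawn fold factors; in path mode each sample gets a
#' gradient position uniform on \[0, 1\] and differential taxa have
#' log-abundance linear in that position.
#'
#' @param params A `sim_params` object from [draw_sim_params()].
#'
#' @return An object of class `community_dataset`: list with `counts`
#'   (integer matrix, rownames = sample ids, colnames = taxon ids),
#'   `metadata` (data.frame with `sample_id` and either `cluster` or
#'   `gradient`), `mode`, `seed`, `params` and (initially `NULL`)
#'   `annotations`.
#' @export
simulate_community <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_samples
  p <- params$n_taxa
  if (n < 2L || p < 2L) stop("need at least 2 samples and 2 taxa")
  if (params$library_size_mean <= 0)
    stop("parameters imply zero expected reads per sample")
  set.seed(params$seed)
  sample_ids <- sprintf("S%03d", seq_len(n))
  taxon_ids <- sprintf("T%04d", seq_len(p))

  lambda <- stats::runif(p, params$baseline_logmean_range[1],
                         params$baseline_logmean_range[2])

  if (params$mode == "cluster") {
    k <- params$n_clusters
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    labels <- rep(paste0("C", seq_len(k)), sizes)
    # per cluster: which taxa respond, and by what (signed log) fold change
    logfac <- matrix(0, k, p)
    for (g in seq_len(k)) {
      de <- stats::runif(p) < params$de_prob
      f <- stats::runif(p, params$de_factor_range[1], params$de_factor_range[2])
      s <- sample(c(-1, 1), p, replace = TRUE)
      logfac[g, de] <- (s * log(f))[de]
    }
    logmu <- matrix(lambda, n, p, byrow = TRUE) +
      logfac[match(labels, paste0("C", seq_len(k))), , drop = FALSE]
    metadata <- data.frame(sample_id = sample_ids, cluster = labels,
                           stringsAsFactors = FALSE)
  } else {
    pos <- stats::runif(n)
    de <- stats::runif(p) < params$de_prob
    f <- stats::runif(p, params$de_factor_range[1], params$de_factor_range[2])
    s <- sample(c(-1, 1), p, replace = TRUE)
    slope <- ifelse(de, s * log(f), 0)
    logmu <- matrix(lambda, n, p, byrow = TRUE) +
      outer(pos - 0.5, slope)
    metadata <- data.frame(sample_id = sample_ids, gradient = pos,
                           stringsAsFactors = FALSE)
  }

  sdlog <- sqrt(log(1 + params$library_size_cv^2))
  meanlog <- log(params$library_size_mean) - sdlog^2 / 2
  lib <- stats::rlnorm(n, meanlog, sdlog)

  m <- exp(logmu)
  prob <- m / rowSums(m)
  mu <- prob * lib
  size <- 1 / params$dispersion
  counts <- matrix(stats::rnbinom(n * p, mu = as.vector(mu), size = size), n, p)
  # guard against (vanishingly unlikely) empty samples
  for (i in which(rowSums(counts) == 0L)) {
    counts[i, ] <- stats::rnbinom(p, mu = mu[i, ], size = size)
    if (sum(counts[i, ]) == 0L) counts[i, which.max(mu[i, ])] <- 1L
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)

  structure(list(counts = counts, metadata = metadata, mode = params$mode,
                 seed = params$seed, params = params, annotations = NULL,
                 degradation = NULL),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("community_dataset: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  if (x$mode == "cluster")
    cat("  clusters:", paste(names(table(x$metadata$cluster)), collapse = " "), "\n")
  else
    cat(sprintf("  gradient range: [%.3f, %.3f]\n",
                min(x$metadata$gradient), max(x$metadata$gradient)))
  if (!is.null(x$annotations))
    cat("  annotations: sequences",
        if (!is.null(x$annotations$tree)) "+ phylogeny", "\n")
  if (!is.null(x$degradation))
    cat("  degraded: levels", paste(sort(unique(x$degradation$assignments$level)),
                                    collapse = "/"), "\n")
  invisible(x)
}

#' Plan of simulated datasets for a full benchmark run
#'
#' The full synthetic study simulates 30 community matrices in the cluster
#' setting and 30 along a continuous path — 60 matrices in total, each
#' with its own seeded parameter draw. `n_per_mode` scales the plan down
#' for desk-sized runs without changing its structure.
#'
#' @param n_per_mode Matrices per setting (default 30).
#' @param base_seed First seed; successive datasets use consecutive seeds.
#' @return Data frame with columns `dataset`, `mode`, `seed`.
#' @export
study_design <- function(n_per_mode = 30L, base_seed = 101L) {
  n_per_mode <- as.integer(n_per_mode)
  stopifnot(n_per_mode >= 1L)
  data.frame(
    dataset = sprintf("sim%02d", seq_len(2L * n_per_mode)),
    mode = rep(c("cluster", "path"), each = n_per_mode),
    seed = base_seed + seq_len(2L * n_per_mode) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-taxon sequences and a phylogeny
#'
#' Builds a random coalescent tree over the taxa and evolves nucleotide
#' sequences along it under a Jukes-Cantor substitution process, so that
#' sequence-aware (k-mer) and tree-aware (UniFrac, PINA) methods can be
#' exercised without external reference data. Only the relative similarity
#' structure among taxa matters for those methods, which this construction
#' provides.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param seq_length Sequence length in bases (>= 20).
#' @param seed Integer seed.
#' @param taxon_ids Optional character vector of tip labels (defaults to
#'   `T0001...`).
#'
#' @return A list of class `taxon_annotations` with `sequences` (named
#'   character vector, alphabet ACGT) and `tree` (rooted `phylo`,
#'   nonnegative branch lengths, tips = taxon ids).
#' @export
simulate_taxa_annotations <- function(n_taxa, seq_length = 150L, seed = 1L,
                                      taxon_ids = NULL) {
  if (n_taxa < 2L) stop("`n_taxa` must be >= 2")
  if (seq_length < 20L) stop("`seq_length` must be >= 20")
  if (is.null(taxon_ids)) taxon_ids <- sprintf("T%04d", seq_len(n_taxa))
  stopifnot(length(taxon_ids) == n_taxa)
  set.seed(as.integer(seed))
  tree <- ape::rcoal(n_taxa, tip.label = taxon_ids)
  tree$edge.length <- pmax(tree$edge.length, 0)
  sim <- phangorn::simSeq(tree, l = as.integer(seq_length), type = "DNA")
  chars <- toupper(as.character(sim))
  seqs <- apply(chars, 1, paste0, collapse = "")
  seqs <- seqs[taxon_ids]
  structure(list(sequences = seqs, tree = tree), class = "taxon_annotations")
}

#' Map external reference sequences to simulated taxa by abundance rank
#'
#' Assigns externally supplied sequences to the taxa of a dataset so that
#' the most abundant external sequence annotates the most abundant taxon,
#' the second most abundant the second, and so on. Taxon abundance is the
#' total relative abundance (column sums of per-sample proportions); ties
#' are broken by taxon identifier order, making the assignment
#' deterministic.
#'
#' @param dataset A `community_dataset`.
#' @param sequences Character vector of external sequences, at least as many
#'   as taxa. If `abundances` is `NULL` the vector is assumed already
#'   ordered from most to least abundant.
#' @param abundances Optional numeric abundances for `sequences`, used to
#'   order them (decreasing).
#'
#' @return The dataset with `annotations$sequences` set (tree, if any, is
#'   kept).
#' @export
map_sequences_by_rank <- function(dataset, sequences, abundances = NULL) {
  stopifnot(inherits(dataset, "community_dataset"))
  p <- ncol(dataset$counts)
  if (length(sequences) < p)
    stop("need at least as many external sequences (", length(sequences),
         ") as taxa (", p, ")")
  if (!is.null(abundances)) {
    stopifnot(length(abundances) == length(sequences))
    sequences <- sequences[order(-abundances)]
  }
  prop <- dataset$counts / rowSums(dataset$counts)
  tot <- colSums(prop)
  rank_order <- order(-tot, colnames(dataset$counts), method = "radix")
  mapped <- character(p)
  mapped[rank_order] <- sequences[seq_len(p)]
  names(mapped) <- colnames(dataset$counts)
  if (is.null(dataset$annotations))
    dataset$annotations <- structure(list(sequences = mapped, tree = NULL),
                                     class = "taxon_annotations")
  else dataset$annotations$sequences <- mapped
  dataset
}
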