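#' Read and write the pipeline's tabular formats
#'
#' Counts and metadata are tab-separated with a header row; the first
#' column holds sample identifiers. Distance matrices are square TSV with
#' matching row/column identifiers and are validated symmetric with zero
#' diagonal on read. Embeddings are TSV with `sample_id`, `axis1`, `axis2`.
#' Writing then reading reproduces the object exactly, including sample
#' and taxon order.
#'
#' @param counts,path,metadata,d,emb Objects/paths as named.
#' @return The written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"), header = TRUE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id(s): ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at row ", df[[1]][bad[1, 1]], ", column ",
         colnames(m)[bad[1, 2]], ": \"", m[bad[1, 1], bad[1, 2]], "\"")
  storage.mode(num) <- "integer"
  dimnames(num) <- list(df[[1]], colnames(m))
  num
}

#' @rdname table_io
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, header = TRUE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a `sample_id` column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id(s) in metadata")
  df
}

#' @rdname table_io
#' @export
write_distance <- function(d, path) {
  d <- as.matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching ids")
  if (any(!is.finite(m)) || max(abs(m - t(m))) > 1e-8 ||
      any(abs(diag(m)) > 1e-12))
    stop("not a valid distance matrix (symmetry/zero-diagonal check failed)")
  m
}

#' @rdname table_io
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(sample_id = rownames(emb), unclass(emb),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname table_io
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- names(s)
  out
}

#' Load a written modern/ancient dataset pair back from disk
#'
#' Reads the files written by the simulation and degradation stages
#' (`<base>_counts.tsv`, `<base>_metadata.tsv`, `<base>_ancient_counts.tsv`,
#' `<base>_degradation_plan.tsv`, `<base>_seqs.fasta`, `<base>_tree.nwk`)
#' into a `list(modern =, ancient =)` of `community_dataset`s suitable for
#' [run_benchmark_grid()] and [transfer_evaluate()].
#'
#' @param base Path prefix of the dataset files.
#' @param seed Seed recorded with the pair.
#' @param mode `"cluster"` or `"path"`.
#' @return List with elements `modern` and `ancient`.
#' @export
read_dataset_pair <- function(base, seed, mode) {
  counts <- read_counts(paste0(base, "_counts.tsv"))
  metadata <- read_metadata(paste0(base, "_metadata.tsv"))
  anc_counts <- read_counts(paste0(base, "_ancient_counts.tsv"))
  dp <- read_metadata(paste0(base, "_degradation_plan.tsv"))
  anns <- structure(list(sequences = read_fasta(paste0(base, "_seqs.fasta")),
                         tree = ape::read.tree(paste0(base, "_tree.nwk"))),
                    class = "taxon_annotations")
  mk <- function(cnt) structure(
    list(counts = cnt, metadata = metadata, mode = mode,
         seed = as.integer(seed), params = NULL, annotations = anns,
         degradation = NULL),
    class = "community_dataset")
  modern <- mk(counts)
  ancient <- mk(anc_counts)
  ancient$degradation <- structure(
    list(assignments = data.frame(sample_id = dp$sample_id,
                                  level = dp$level,
                                  stringsAsFactors = FALSE),
         noise_halfwidth = 0.03, seed = as.integer(seed)),
    class = "degradation_plan")
  list(modern = modern, ancient = ancient)
}

#' Preprocess an empirical composition matrix for the benchmark
#'
#' Applies, in this fixed order: (1) optional class balancing — every class
#' of a categorical variable is subsampled to the smallest class size;
#' (2) capping the number of samples at `max_samples` by seeded random
#' subsampling; (3) taxa reduction — the smallest integer constant c >= 0
#' is subtracted from every cell (floored at zero) such that the number of
#' taxa with nonzero totals falls within `taxa_target`, then all-zero taxa
#' are dropped (no subtraction when already below the lower bound; the
#' constant-subtraction never reorders surviving taxa totals); (4) dropping
#' samples with fewer than `min_taxa_per_sample` detected taxa.
#'
#' @param counts Nonnegative integer matrix, samples x taxa.
#' @param metadata Data frame with `sample_id` and either `cluster`
#'   (categorical) or `gradient` (numeric).
#' @param max_samples Sample cap (default 125).
#' @param taxa_target Target interval for the number of retained taxa
#'   (default `c(1000, 4000)`).
#' @param min_taxa_per_sample Minimum detected taxa per retained sample
#'   (default 20).
#' @param balance_classes Balance class sizes when metadata is categorical
#'   (default `TRUE`).
#' @param seed Integer seed for the subsampling.
#' @return A `community_dataset` with the filtered counts and metadata.
#' @export
preprocess_empirical <- function(counts, metadata, max_samples = 125L,
                                 taxa_target = c(1000L, 4000L),
                                 min_taxa_per_sample = 20L,
                                 balance_classes = TRUE, seed = 1L) {
  stopifnot(is.matrix(counts), nrow(counts) >= 4,
            is.data.frame(metadata), "sample_id" %in% names(metadata))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  mode <- if ("cluster" %in% names(metadata)) "cluster" else "path"
  set.seed(as.integer(seed))

  keep <- seq_len(nrow(counts))
  if (mode == "cluster" && balance_classes) {
    cl <- metadata$cluster
    nmin <- min(table(cl))
    keep <- sort(unlist(lapply(unique(cl), function(g)
      resample(which(cl == g), nmin))))
  }
  if (length(keep) > max_samples)
    keep <- sort(resample(keep, max_samples))
  counts <- counts[keep, , drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]

  n_taxa_at <- function(c) sum(colSums(pmax(counts - c, 0)) > 0)
  if (n_taxa_at(0) > taxa_target[2]) {
    lo <- 0L; hi <- as.integer(max(counts))
    while (lo < hi) {                      # smallest c with count <= upper
      mid <- (lo + hi) %/% 2L
      if (n_taxa_at(mid) <= taxa_target[2]) hi <- mid else lo <- mid + 1L
    }
    counts <- pmax(counts - lo, 0L)
  }
  counts <- counts[, colSums(counts) > 0, drop = FALSE]

  rich <- rowSums(counts > 0)
  ok <- rich >= min_taxa_per_sample
  if (!any(ok)) stop("all samples filtered out by the richness threshold")
  counts <- counts[ok, , drop = FALSE]
  metadata <- metadata[ok, , drop = FALSE]
  storage.mode(counts) <- "integer"

  structure(list(counts = counts, metadata = metadata, mode = mode,
                 seed = as.integer(seed), params = NULL, annotations = NULL,
                 degradation = NULL),
            class = "community_dataset")
}
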