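#' Count transformation methods
#'
#' The thirteen transformations benchmarked by the pipeline, behind one
#' dispatch interface. Compositional methods (`prop`, `hellinger`,
#' `chi_square`, `clr`, `rclr`) and rarefaction operate sample-wise;
#' scaling-factor methods (`css`, `tmm`, `tmmwsp`, `wrench`, `gmpr`)
#' estimate per-sample size/normalization factors; `vst` applies a
#' closed-form negative-binomial variance-stabilizing map with a fitted
#' mean-dispersion trend; `kmer` replaces the taxon feature space by
#' sequence k-mer proportions.
#'
#' @param counts Nonnegative integer matrix, samples in rows, taxa in
#'   columns (dimnames required).
#' @param method One of `"prop"`, `"rarefy"`, `"hellinger"`, `"chi_square"`,
#'   `"css"`, `"clr"`, `"rclr"`, `"vst"`, `"tmm"`, `"tmmwsp"`, `"wrench"`,
#'   `"gmpr"`, `"kmer"`.
#' @param rarefy_depth Rarefaction depth: `"min"` (default, the smallest
#'   sample total) or a positive integer no larger than every sample total.
#' @param clr_pseudocount Pseudocount added before the clr log (default 1);
#'   may be 0 only if the matrix has no zeros.
#' @param kmer_k k-mer length for `method = "kmer"` (default 5).
#' @param sequences Named character vector of taxon sequences (required for
#'   `"kmer"`).
#' @param wrench_groups Optional per-sample group labels for `"wrench"`;
#'   all samples form one group when omitted.
#' @param css_quantile Optional fixed quantile for `"css"`; by default a
#'   data-driven quantile is chosen (see Details).
#' @param seed Integer seed (used by `"rarefy"`).
#'
#' @details
#' `css` uses cumulative-sum scaling: each sample is scaled by the sum of
#' its counts up to a quantile of its nonzero counts. The quantile is
#' chosen data-driven as the smallest p >= 0.50 at which the across-sample
#' instability profile (median absolute deviation of per-sample quantiles
#' from their mean, over a percent grid) starts growing by more than 10%
#' per step, falling back to 0.50 when the profile is stable.
#'
#' `vst` estimates size factors as medians of ratios to per-taxon geometric
#' means (computed on counts + 0.5 so sparse matrices are handled), obtains
#' moment dispersion estimates per taxon, fits the trend
#' dispersion = a0/mean + a1 by ordinary least squares, and applies the
#' closed-form variance-stabilizing map for that trend on the normalized
#' counts (log2 scale).
#'
#' `tmm`/`tmmwsp` obtain normalization factors from
#' [edgeR::calcNormFactors()] and return `log2(CPM + 1)` computed on
#' effective library sizes (library size times normalization factor).
#'
#' `wrench` is a ratio-based compositional scale estimator: each sample's
#' raw factor is the geometric mean of its nonzero taxon
#' proportion-to-average-proportion ratios, shrunk toward its group mean by
#' a normal-normal empirical Bayes weight; the net per-sample factor
#' (compositional factor times library size, rescaled to geometric mean 1)
#' divides the counts.
#'
#' `gmpr` size factors are geometric means over samples of median pairwise
#' count ratios across shared nonzero taxa.
#'
#' @return A real matrix (samples x features) with attributes `method` and,
#'   for `rarefy`, `depth`. For `kmer` the columns are k-mers; otherwise
#'   they are the input taxa.
#' @export
transform_counts <- function(counts, method,
                             rarefy_depth = "min",
                             clr_pseudocount = 1,
                             kmer_k = 5L,
                             sequences = NULL,
                             wrench_groups = NULL,
                             css_quantile = NULL,
                             seed = NULL) {
  method <- match.arg(method, transform_methods())
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("T%04d", seq_len(ncol(counts)))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite nonnegative integers")
  if (any(rowSums(counts) == 0)) stop("all-zero sample(s) present")
  out <- switch(method,
    prop = counts / rowSums(counts),
    hellinger = sqrt(counts / rowSums(counts)),
    chi_square = {
      # x_ij * sqrt(grand total) / (row total_i * sqrt(column total_j))
      sweep(counts / rowSums(counts), 2, sqrt(colSums(counts)), "/") *
        sqrt(sum(counts))
    },
    rarefy = .t_rarefy(counts, rarefy_depth, seed),
    css = .t_css(counts, css_quantile),
    clr = .t_clr(counts, clr_pseudocount),
    rclr = .t_rclr(counts),
    vst = .t_vst(counts),
    tmm = .t_tmm(counts, "TMM"),
    tmmwsp = .t_tmm(counts, "TMMwsp"),
    wrench = .t_wrench(counts, wrench_groups),
    gmpr = .t_gmpr(counts),
    kmer = .t_kmer(counts, sequences, kmer_k)
  )
  if (any(!is.finite(out)))
    stop("transform `", method, "` produced non-finite values")
  attr(out, "method") <- method
  out
}

#' @rdname transform_counts
#' @export
transform_methods <- function() {
  c("prop", "rarefy", "hellinger", "chi_square", "css", "clr", "rclr",
    "vst", "tmm", "tmmwsp", "wrench", "gmpr", "kmer")
}

.t_rarefy <- function(counts, depth, seed) {
  tot <- rowSums(counts)
  if (identical(depth, "min")) depth <- min(tot)
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  low <- which(tot < depth)
  if (length(low))
    stop("rarefaction depth ", depth, " exceeds the total of sample(s): ",
         paste(rownames(counts)[low], collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- suppressWarnings(vegan::rrarefy(counts, depth))
  storage.mode(out) <- "double"
  attr(out, "depth") <- depth
  out
}

.t_clr <- function(counts, pc) {
  if (pc < 0) stop("`clr_pseudocount` must be >= 0")
  if (pc == 0 && any(counts == 0))
    stop("clr with zero entries requires a positive pseudocount")
  lg <- log(counts + pc)
  lg - rowMeans(lg)
}

.t_rclr <- function(counts) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    nz <- counts[i, ] > 0
    lg <- log(counts[i, nz])
    out[i, nz] <- lg - mean(lg)
  }
  out
}

.css_quantile <- function(counts, grid = seq(0.01, 0.99, by = 0.01)) {
  q <- vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    stats::quantile(x[x > 0], grid, names = FALSE, type = 7)
  }, numeric(length(grid)))
  ref <- rowMeans(q)
  instab <- apply(abs(q - ref), 1, stats::median)
  lo <- which(grid >= 0.50)
  for (j in lo[-length(lo)]) {
    if (instab[j] > 0 && (instab[j + 1] - instab[j]) > 0.10 * instab[j])
      return(grid[j])
  }
  0.50
}

.t_css <- function(counts, quantile = NULL) {
  if (is.null(quantile)) quantile <- .css_quantile(counts)
  s <- vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    nz <- x[x > 0]
    qi <- stats::quantile(nz, quantile, names = FALSE, type = 7)
    sum(x[x <= qi])
  }, numeric(1))
  if (any(s == 0)) stop("zero cumulative-sum scaling factor")
  out <- counts / s * stats::median(s)
  attr(out, "css_quantile") <- quantile
  out
}

.vst_fit <- function(counts) {
  gm <- exp(colMeans(log(counts + 0.5)))
  sf <- apply(sweep(counts + 0.5, 2, gm, "/"), 1, stats::median)
  sf <- sf / exp(mean(log(sf)))
  q <- counts / sf
  mu <- colMeans(q)
  v <- apply(q, 2, stats::var)
  disp <- (v - mu) / mu^2
  keep <- is.finite(disp) & disp > 0 & mu > 0
  if (sum(keep) >= 3) {
    X <- cbind(1 / mu[keep], 1)
    ab <- solve(crossprod(X), crossprod(X, disp[keep]))
    a0 <- max(ab[1], 0)
    a1 <- max(ab[2], 1e-8)
  } else {
    a0 <- 0
    a1 <- max(mean(disp[keep]), 0.1, na.rm = TRUE)
  }
  list(size_factors = sf, a0 = a0, a1 = a1)
}

.t_vst <- function(counts) {
  fit <- .vst_fit(counts)
  q <- counts / fit$size_factors
  a0 <- fit$a0; a1 <- fit$a1
  log2((1 + a0 + 2 * a1 * q + 2 * sqrt(a1 * q * (1 + a0 + a1 * q))) / (4 * a1))
}

.t_tmm <- function(counts, method) {
  y <- t(counts)
  nf <- edgeR::calcNormFactors(y, method = method)
  eff <- rowSums(counts) * nf
  log2(counts / eff * 1e6 + 1)
}

.t_wrench <- function(counts, groups) {
  n <- nrow(counts)
  if (is.null(groups)) groups <- rep("all", n)
  stopifnot(length(groups) == n)
  p <- counts / rowSums(counts)
  pbar <- colMeans(p)
  ok <- pbar > 0
  lr <- vector("list", n)
  ls_raw <- numeric(n)
  svar <- numeric(n)
  for (i in seq_len(n)) {
    nz <- which(p[i, ] > 0 & ok)
    l <- log(p[i, nz] / pbar[nz])
    ls_raw[i] <- mean(l)
    svar[i] <- if (length(l) > 1) stats::var(l) / length(l) else 0
  }
  ls <- ls_raw
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    gmean <- mean(ls_raw[idx])
    gvar <- max(stats::var(ls_raw[idx]) - mean(svar[idx]), 0)
    w <- svar[idx] / (svar[idx] + gvar)
    w[!is.finite(w)] <- 1
    ls[idx] <- w * gmean + (1 - w) * ls_raw[idx]
  }
  s <- exp(ls - mean(ls))
  tau <- s * rowSums(counts)
  tau <- tau / exp(mean(log(tau)))
  counts / tau
}

.gmpr_factors <- function(counts) {
  n <- nrow(counts)
  s <- numeric(n)
  for (i in seq_len(n)) {
    r <- numeric(0)
    for (k in seq_len(n)) {
      if (k == i) next
      shared <- counts[i, ] > 0 & counts[k, ] > 0
      if (!any(shared)) next
      r <- c(r, stats::median(counts[i, shared] / counts[k, shared]))
    }
    if (!length(r))
      stop("sample ", rownames(counts)[i],
           " shares no nonzero taxa with any other sample")
    s[i] <- exp(mean(log(r)))
  }
  s
}

.t_gmpr <- function(counts) {
  counts / .gmpr_factors(counts)
}

.t_kmer <- function(counts, sequences, k) {
  if (is.null(sequences)) stop("kmer transform requires taxon sequences")
  k <- as.integer(k)
  if (k < 1L) stop("`kmer_k` must be >= 1")
  miss <- setdiff(colnames(counts), names(sequences))
  if (length(miss))
    stop("missing sequence(s) for taxa: ", paste(utils::head(miss, 5), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(sequences[colnames(counts)])
  km <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  kfreq <- km / rowSums(km)
  prof <- counts %*% kfreq
  prof / rowSums(prof)
}
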