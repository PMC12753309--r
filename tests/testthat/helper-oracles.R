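# Independent brute-force oracles used by the unit tests and the
# acceptance suite. Everything here is written directly from the defining
# formulas, without calling the package's implementation paths.

rand_counts <- function(seed, n = 6, p = 10, lambda = 8, zero_frac = 0.3) {
  set.seed(seed)
  x <- matrix(rpois(n * p, lambda), n, p)
  x[sample(n * p, round(zero_frac * n * p))] <- 0L
  empty <- rowSums(x) == 0
  x[empty, 1] <- 1L
  storage.mode(x) <- "integer"
  dimnames(x) <- list(sprintf("S%03d", 1:n), sprintf("T%04d", 1:p))
  x
}

toy_dataset <- function(seed = 1, n = 24, p = 40, k = 3, mode = "cluster",
                        de_prob = 0.3, de_factor = c(3, 6)) {
  params <- draw_sim_params(seed, mode, overrides = list(
    n_samples = as.integer(n), n_taxa = as.integer(p),
    n_clusters = as.integer(k), de_prob = de_prob,
    de_factor_range = de_factor))
  simulate_community(params)
}

# empirical-like fixture: an abundant core plus a long tail of rare taxa
make_empirical_counts <- function(seed, n = 200, n_core = 80, n_rare = 320) {
  set.seed(seed)
  core <- matrix(rnbinom(n * n_core, mu = 30, size = 0.5), n, n_core)
  rare <- matrix(0L, n, n_rare)
  for (j in seq_len(n_rare)) {
    k <- sample(1:3, 1)
    rare[cbind(sample(n, k), j)] <- sample(1:2, k, replace = TRUE)
  }
  x <- cbind(core, rare)
  dimnames(x) <- list(sprintf("E%03d", seq_len(n)),
                      sprintf("T%04d", seq_len(n_core + n_rare)))
  storage.mode(x) <- "integer"
  x
}

pairloop <- function(m, f) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- f(m[i, ], m[j, ])
  d
}

# ---- transform oracles -----------------------------------------------------

oracle_prop <- function(x) t(apply(x, 1, function(v) v / sum(v)))

oracle_hellinger <- function(x) sqrt(oracle_prop(x))

oracle_chi_square <- function(x) {
  N <- sum(x)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    out[i, j] <- x[i, j] * sqrt(N) / (sum(x[i, ]) * sqrt(sum(x[, j])))
  out
}

oracle_clr <- function(x, pc = 1) {
  out <- x * 0
  for (i in seq_len(nrow(x))) {
    lg <- log(x[i, ] + pc)
    out[i, ] <- lg - mean(lg)
  }
  out
}

oracle_rclr <- function(x) {
  out <- x * 0
  for (i in seq_len(nrow(x))) {
    nz <- x[i, ] > 0
    out[i, nz] <- log(x[i, nz]) - mean(log(x[i, nz]))
  }
  out
}

oracle_css <- function(x, quantile_p) {
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    nz <- sort(x[i, x[i, ] > 0])
    qi <- stats::quantile(nz, quantile_p, names = FALSE, type = 7)
    s[i] <- sum(x[i, x[i, ] <= qi])
  }
  x / s * stats::median(s)
}

# closed-form NB variance-stabilizing map with trend disp = a0/mu + a1,
# all nuisance fits redone from the definitions (normal equations by hand)
oracle_vst <- function(x) {
  n <- nrow(x); p <- ncol(x)
  gm <- numeric(p)
  for (j in seq_len(p)) gm[j] <- exp(mean(log(x[, j] + 0.5)))
  sf <- numeric(n)
  for (i in seq_len(n)) sf[i] <- stats::median((x[i, ] + 0.5) / gm)
  sf <- sf / exp(mean(log(sf)))
  q <- x / sf
  mu <- colMeans(q)
  v <- apply(q, 2, stats::var)
  disp <- (v - mu) / mu^2
  keep <- is.finite(disp) & disp > 0 & mu > 0
  if (sum(keep) >= 3) {
    u <- 1 / mu[keep]; y <- disp[keep]; m <- sum(keep)
    # least squares for y = a0*u + a1 via explicit normal equations
    det <- sum(u^2) * m - sum(u)^2
    a0 <- (sum(u * y) * m - sum(u) * sum(y)) / det
    a1 <- (sum(u^2) * sum(y) - sum(u) * sum(u * y)) / det
    a0 <- max(a0, 0); a1 <- max(a1, 1e-8)
  } else {
    a0 <- 0; a1 <- max(mean(disp[keep]), 0.1, na.rm = TRUE)
  }
  log2((1 + a0 + 2 * a1 * q + 2 * sqrt(a1 * q * (1 + a0 + a1 * q))) / (4 * a1))
}

# trimmed mean of M-values, following the published algorithm
# (30% trim on M, 5% on A, inverse-asymptotic-variance weights,
# reference = sample whose upper quartile is closest to the mean)
oracle_tmm_factors <- function(counts) {
  y <- t(counts); lib <- colSums(y)
  f75 <- apply(y, 2, function(v) stats::quantile(v, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    obs <- y[, j] / lib[j]
    nr <- y[, ref] / lib[ref]
    keep0 <- obs > 0 & nr > 0
    M <- log2(obs[keep0] / nr[keep0])
    A <- 0.5 * log2(obs[keep0] * nr[keep0])
    w <- (lib[j] - y[keep0, j]) / (lib[j] * y[keep0, j]) +
      (lib[ref] - y[keep0, ref]) / (lib[ref] * y[keep0, ref])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum((M / w)[keep]) / sum((1 / w)[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# singleton-pairing variant (reference = max column sum of sqrt counts;
# singleton positive counts paired across samples in decreasing order;
# unshrunken trimmed weighted mean on the augmented ratio set)
oracle_tmmwsp_factors <- function(counts) {
  y <- t(counts); lib <- colSums(y)
  allzero <- rowSums(y > 0) == 0
  y <- y[!allzero, , drop = FALSE]
  ref <- which.max(colSums(sqrt(y)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    obs <- y[, j]; refc <- y[, ref]
    lo <- lib[j]; lr <- lib[ref]
    pos.obs <- obs > 1e-14; pos.ref <- refc > 1e-14
    npos <- 2L * pos.obs + pos.ref
    drop0 <- npos == 0L
    obs <- obs[!drop0]; refc <- refc[!drop0]; npos <- npos[!drop0]
    zero.obs <- npos == 1L; zero.ref <- npos == 2L
    k <- zero.obs | zero.ref
    nsing <- min(sum(zero.obs), sum(zero.ref))
    if (nsing > 0L) {
      refk <- sort(refc[k], decreasing = TRUE)[1:nsing]
      obsk <- sort(obs[k], decreasing = TRUE)[1:nsing]
      obs <- c(obs[!k], obsk); refc <- c(refc[!k], refk)
    } else {
      obs <- obs[!k]; refc <- refc[!k]
    }
    n <- length(obs)
    if (n == 0L) return(1)
    op <- obs / lo; rp <- refc / lr
    M <- log2(op / rp); A <- 0.5 * log2(op * rp)
    if (max(abs(M)) < 1e-6) return(1)
    Ms <- log2(((obs + 0.5) / (lo + 0.5)) / ((refc + 0.5) / (lr + 0.5)))
    o.M <- order(M, Ms); o.A <- order(A)
    loM <- as.integer(n * 0.3) + 1L; hiM <- n + 1L - loM
    loA <- as.integer(n * 0.05) + 1L; hiA <- n + 1L - loA
    keep <- logical(n)
    keep[o.M[loM:hiM]] <- TRUE
    keepA <- logical(n); keepA[o.A[loA:hiA]] <- TRUE
    keep <- keep & keepA
    v <- (1 - op[keep]) / op[keep] / lo + (1 - rp[keep]) / rp[keep] / lr
    w <- (1 + 1e-6) / (v + 1e-6)
    2^(sum(w * M[keep]) / sum(w))
  }, numeric(1))
  f / exp(mean(log(f)))
}

oracle_logcpm <- function(counts, factors) {
  eff <- rowSums(counts) * factors
  out <- counts * 0
  for (i in seq_len(nrow(counts)))
    out[i, ] <- log2(counts[i, ] / eff[i] * 1e6 + 1)
  out
}

oracle_wrench <- function(x, groups = NULL) {
  n <- nrow(x)
  if (is.null(groups)) groups <- rep("all", n)
  p <- oracle_prop(x)
  pbar <- colMeans(p)
  ls_raw <- svar <- numeric(n)
  for (i in seq_len(n)) {
    nz <- which(p[i, ] > 0 & pbar > 0)
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
  tau <- s * rowSums(x)
  tau <- tau / exp(mean(log(tau)))
  x / tau
}

oracle_gmpr_factors <- function(x) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    r <- c()
    for (k in seq_len(n)) {
      if (k == i) next
      sh <- x[i, ] > 0 & x[k, ] > 0
      if (any(sh)) r <- c(r, stats::median(x[i, sh] / x[k, sh]))
    }
    s[i] <- exp(mean(log(r)))
  }
  s
}

oracle_kmer <- function(x, seqs, k) {
  seqs <- seqs[colnames(x)]
  kmers <- sort(unique(unlist(lapply(seqs, function(s) {
    vapply(seq_len(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1), "")
  }))))
  kf <- matrix(0, length(seqs), length(kmers),
               dimnames = list(names(seqs), kmers))
  for (t in seq_along(seqs)) {
    s <- seqs[[t]]
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      kf[t, w] <- kf[t, w] + 1
    }
    kf[t, ] <- kf[t, ] / sum(kf[t, ])
  }
  prof <- x %*% kf
  prof / rowSums(prof)
}

# ---- distance oracles ------------------------------------------------------

oracle_bray <- function(m) pairloop(m, function(a, b) sum(abs(a - b)) / sum(a + b))

oracle_canberra <- function(m) pairloop(m, function(a, b) {
  nz <- a > 0 | b > 0
  sum((abs(a - b) / (a + b))[nz]) / sum(nz)
})

oracle_kulczynski <- function(m) pairloop(m, function(a, b)
  1 - 0.5 * (sum(pmin(a, b)) / sum(a) + sum(pmin(a, b)) / sum(b)))

oracle_horn <- function(m) pairloop(m, function(a, b)
  1 - 2 * sum(a * b) /
    ((sum(a^2) / sum(a)^2 + sum(b^2) / sum(b)^2) * sum(a) * sum(b)))

oracle_gower <- function(m) {
  rng <- apply(m, 2, function(v) diff(range(v)))
  std <- sweep(sweep(m, 2, apply(m, 2, min)), 2, ifelse(rng > 0, rng, 1), "/")
  pairloop(std, function(a, b) mean(abs(a - b)))
}

oracle_alt_gower <- function(m) pairloop(m, function(a, b) {
  nz <- a > 0 | b > 0
  sum(abs(a - b)[nz]) / sum(nz)
})

oracle_chao <- function(x) pairloop(x, function(xi, xk) {
  shared <- xi > 0 & xk > 0
  if (!any(shared)) return(1)
  U <- function(a, b, Na, Nb) {
    a1 <- sum(shared & b == 1); a2 <- sum(shared & b == 2)
    u <- sum(a[shared]) / Na +
      (Nb - 1) / Nb * a1 / (2 * max(a2, 1)) * sum(a[shared & b == 1]) / Na
    min(u, 1)
  }
  Ui <- U(xi, xk, sum(xi), sum(xk)); Uk <- U(xk, xi, sum(xk), sum(xi))
  if (Ui == 0 || Uk == 0) return(1)
  1 - Ui * Uk / (Ui + Uk - Ui * Uk)
})

oracle_cor_dist <- function(m, method) pairloop(m, function(a, b)
  1 - stats::cor(a, b, method = method))

oracle_iaw <- function(m, assoc) {
  p <- t(apply(m, 1, function(v) v / sum(v)))
  self <- numeric(nrow(m))
  for (i in seq_len(nrow(m)))
    self[i] <- sum(outer(p[i, ], p[i, ]) * assoc)
  d <- matrix(0, nrow(m), nrow(m))
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    s <- sum(outer(p[i, ], p[j, ]) * assoc) / sqrt(self[i] * self[j])
    d[i, j] <- d[j, i] <- 1 - min(max(s, 0), 1)
  }
  d
}

# per-edge tip masses computed independently via phangorn::Descendants
oracle_unifrac <- function(m, tree, variant, alpha = 0.5) {
  p <- t(apply(m, 1, function(v) v / sum(v)))
  colnames(p) <- colnames(m)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  E <- vapply(desc, function(tips)
    rowSums(p[, tree$tip.label[tips], drop = FALSE]), numeric(nrow(p)))
  len <- tree$edge.length
  pairloop(p, function(a, b) NA) -> d   # shape only
  for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
    A <- E[i, ]; B <- E[j, ]; msum <- A + B; dif <- abs(A - B)
    val <- if (variant == "weighted") {
      sum(len * dif) / sum(len * msum)
    } else if (variant == "generalized") {
      nz <- msum > 0
      sum(len[nz] * msum[nz]^alpha * dif[nz] / msum[nz]) /
        sum(len[nz] * msum[nz]^alpha)
    } else {
      ok <- msum > 0 & msum < 2
      w <- 1 / sqrt(msum[ok] * (2 - msum[ok]))
      sum(len[ok] * dif[ok] * w) / sum(len[ok] * msum[ok] * w)
    }
    d[i, j] <- d[j, i] <- val
  }
  diag(d) <- 0
  d
}

# ---- PERMANOVA oracle ------------------------------------------------------

# explicit Gower centering + hat-matrix projection
oracle_permanova_F <- function(d, variable) {
  d <- as.matrix(d); n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  if (is.factor(variable) || is.character(variable)) {
    X <- stats::model.matrix(~ factor(variable))
    dfm <- nlevels(factor(variable)) - 1
  } else {
    X <- stats::model.matrix(~ variable)
    dfm <- 1
  }
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssm <- sum(diag(H %*% G %*% H))
  sst <- sum(diag(G))
  dfr <- n - dfm - 1
  (ssm / dfm) / ((sst - ssm) / dfr)
}

# stress-1 recomputation on a final NMDS configuration
oracle_stress1 <- function(d, coords) {
  dv <- as.vector(stats::as.dist(as.matrix(d)))
  ev <- as.vector(stats::dist(coords))
  o <- order(dv)
  ir <- stats::isoreg(dv[o], ev[o])
  sqrt(sum((ir$yf - ev[o])^2) / sum(ev^2))
}
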