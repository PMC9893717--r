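# Independent oracles and fixture builders, kept deliberately naive:
# exhaustive search and element-by-element scans, no shared code with the
# package implementations they check.

# ---- modularity oracle -----------------------------------------------------

# Modularity of a labeled partition, directly from the definition.
oracleQ <- function(A, labels) {
  k <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  q / (2 * m)
}

# Exhaustive recursive bisection: at every stage try all 2^(n-1) sign
# assignments of the group, take the best modularity gain, stop when no
# split has a positive gain. Returns the partition labels.
oraclePartition <- function(A, tol = 1e-12) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(A) / 2
  B <- A - outer(k, k) / (2 * m)
  labels <- integer(n)
  nextLab <- 0L
  recurse <- function(nodes) {
    nn <- length(nodes)
    if (nn == 1L) {
      nextLab <<- nextLab + 1L
      labels[nodes] <<- nextLab
      return(invisible())
    }
    Bg <- B[nodes, nodes, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    best <- -Inf; bestS <- NULL
    for (code in 0:(2^(nn - 1L) - 1L)) {
      bits <- as.integer(intToBits(code))[seq_len(nn - 1L)]
      s <- c(1, ifelse(bits == 1L, 1, -1))
      if (all(s == 1)) next
      dQ <- drop(crossprod(s, Bg %*% s)) / (4 * m)
      if (dQ > best) { best <- dQ; bestS <- s }
    }
    if (is.null(bestS) || best <= tol) {
      nextLab <<- nextLab + 1L
      labels[nodes] <<- nextLab
      return(invisible())
    }
    recurse(nodes[bestS > 0])
    recurse(nodes[bestS < 0])
  }
  recurse(seq_len(n))
  labels
}

# ---- small graph builders --------------------------------------------------

cliqueUnion <- function(sizes) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    A[idx, idx] <- 1
    at <- at + s
  }
  diag(A) <- 0
  A
}

ringGraph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

completeGraph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

plantedGraph <- function(sizes, pin, pout, seed) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- if (lab[i] == lab[j]) pin else pout
    A[i, j] <- A[j, i] <- stats::runif(1) * w
  }
  A
}

# ---- RQA oracle ------------------------------------------------------------

# Exhaustive run-length scan of every diagonal and every column of a binary
# matrix; returns the five measures computed literally from the scans.
oracleRqa <- function(P, minLine = 2L, includeLoi = TRUE) {
  n <- nrow(P)
  dlens <- integer(0)
  for (off in (-(n - 1L)):(n - 1L)) {
    if (!includeLoi && off == 0L) next
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      v <- if (j >= 1L && j <= n) P[i, j] else NA
      if (identical(v, 1L) || identical(v, 1)) run <- run + 1L
      else { if (run > 0L) dlens <- c(dlens, run); run <- 0L }
    }
    if (run > 0L) dlens <- c(dlens, run)
  }
  vlens <- integer(0); wlens <- integer(0)
  for (j in seq_len(n)) {
    run1 <- 0L; run0 <- 0L
    for (i in seq_len(n)) {
      if (P[i, j] == 1) {
        run1 <- run1 + 1L
        if (run0 > 0L) { wlens <- c(wlens, run0); run0 <- 0L }
      } else {
        run0 <- run0 + 1L
        if (run1 > 0L) { vlens <- c(vlens, run1); run1 <- 0L }
      }
    }
    if (run1 > 0L) vlens <- c(vlens, run1)
    if (run0 > 0L) wlens <- c(wlens, run0)
  }
  total <- sum(P)
  dTotal <- if (includeLoi) total else total - sum(diag(P))
  list(rr = total / n^2,
       det = if (dTotal > 0) sum(dlens[dlens >= minLine]) / dTotal else 0,
       div = if (length(dlens)) 1 / max(dlens) else NA_real_,
       lam = if (total > 0) sum(vlens[vlens >= minLine]) / total else 0,
       wMean = if (length(wlens)) mean(wlens) else 0)
}

randomRecurrencePlot <- function(n, density, seed) {
  set.seed(seed)
  P <- matrix(0L, n, n)
  P[upper.tri(P)] <- as.integer(stats::runif(n * (n - 1) / 2) < density)
  P <- P + t(P)
  diag(P) <- 1L
  new("RecurrencePlot", P = P, epsilon = 1, embeddingDimension = 1L,
      embeddingDelay = 1L)
}

# ---- misc ------------------------------------------------------------------

adjustedAgreement <- function(a, b) mclust::adjustedRandIndex(a, b)

smallSynth <- function(K = 3L, nm = 8L, F = 1500L, pA = 0.95, pBg = 0.01,
                       seed = 100L + K, epoch = 20L) {
  synthConfig(nNeurons = nm * K, nFrames = F,
              membership = split(seq_len(nm * K), rep(seq_len(K), each = nm)),
              epochLength = epoch, sequence = seq_len(K),
              pActive = pA, pBackground = pBg, seed = seed)
}

.runsRejectsOracle <- function(x, alpha = 0.05) {
  tryCatch(runsTest(x)$p.value < alpha, error = function(e) FALSE)
}
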