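#' Correlation distance between neuron activity vectors
#'
#' Pairwise distance `d_ij = 1 - r_ij` with `r` the Pearson correlation of the
#' binary activity rows (on 0/1 data this is the phi coefficient). Distances
#' lie in `[0, 2]`: 0 for perfectly correlated, 1 for uncorrelated, 2 for
#' perfectly anticorrelated activity. Zero-variance neurons (silent or always
#' active), for which the correlation is undefined, are excluded and reported
#' in the `"excluded"` attribute of the result.
#'
#' @param raster a [Raster-class] with at least 2 neurons.
#' @return Square distance matrix over the non-degenerate neurons, with
#'   attributes `"excluded"` (indices of excluded neurons) and `"neurons"`
#'   (original indices of the rows kept).
#' @export
correlationDistance <- function(raster) {
  stopifnot(is(raster, "Raster"))
  a <- activityMatrix(raster)
  if (nrow(a) < 2L) stop("need at least 2 neurons")
  v <- apply(a, 1L, stats::var)
  excluded <- which(v == 0)
  keep <- which(v > 0)
  if (length(keep) < 2L)
    stop("fewer than 2 neurons with non-constant activity")
  r <- stats::cor(t(a[keep, , drop = FALSE]))
  d <- 1 - r
  d[d < 0] <- 0
  diag(d) <- 0
  structure(d, excluded = as.integer(excluded), neurons = as.integer(keep))
}

# Solve sum(exp(-ex / sigma)) = target for sigma by bisection.
# ex are the neighbor distances minus rho (>= 0, first entry 0).
.solveSigma <- function(ex, target, tol = 1e-5, maxit = 64L) {
  f <- function(s) sum(exp(-ex / s))
  lo <- 1e-12
  # f is increasing in sigma; if already >= target at sigma -> 0 (ties at
  # rho), keep the smallest scale: exact-rho neighbors get weight 1.
  if (f(lo) >= target) return(lo)
  hi <- 1
  it <- 0L
  while (f(hi) < target && it < maxit) { hi <- hi * 2; it <- it + 1L }
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - target) < tol) return(mid)
    if (val < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fuzzy nearest-neighbor graph over activity vectors
#'
#' Builds the weighted functional-connectivity graph. For every node the
#' `nNeighbors` nearest neighbors (ties broken by lower index) receive local
#' weights `w_ij = exp(-max(0, d_ij - rho_i) / sigma_i)`, where `rho_i` is the
#' distance to the nearest neighbor (so that neighbor always gets weight 1)
#' and `sigma_i` is calibrated by bisection so the local weights sum to
#' `log2(nNeighbors)`. The two directed weights are then combined by the
#' probabilistic union `w = w_ij + w_ji - w_ij * w_ji`.
#'
#' @param distances square distance matrix (e.g. from
#'   [correlationDistance()]); an `"excluded"` attribute, if present, is
#'   propagated.
#' @param nNeighbors local neighborhood size (>= 2 and < number of nodes).
#'   Small values focus the graph on fine local structure.
#' @return An [AdjacencyGraph-class].
#' @export
fuzzyKnnGraph <- function(distances, nNeighbors = 10L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  nNeighbors <- as.integer(nNeighbors)
  if (nNeighbors < 2L || nNeighbors >= n)
    stop("nNeighbors must be >= 2 and < number of nodes (", n, ")")
  target <- log2(nNeighbors)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    nb <- order(d)[seq_len(nNeighbors)]      # stable: ties -> lower index
    ex <- pmax(0, d[nb] - d[nb[1L]])
    sigma <- .solveSigma(ex, target)
    W[i, nb] <- exp(-ex / sigma)
  }
  U <- W + t(W) - W * t(W)
  adjacencyGraph(U, excluded = attr(distances, "excluded") %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Modularity matrix
#'
#' Full matrix `B_ij = A_ij - k_i k_j / (2m)` of a weighted graph (rows sum
#' to zero), or the generalized group-restricted matrix
#' `B(g)_ij = B_ij - delta_ij sum_{k in g} B_ik` used when recursively
#' splitting a subgraph.
#'
#' @param graph an [AdjacencyGraph-class] with positive total weight.
#' @param group optional integer vector of node indices for the generalized
#'   matrix.
#' @return A [ModularityMatrix-class].
#' @export
modularityMatrix <- function(graph, group = NULL) {
  stopifnot(is(graph, "AdjacencyGraph"))
  A <- graph@weights
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m <= 0) stop("graph has no edges")
  B <- A - outer(k, k) / (2 * m)
  if (is.null(group)) {
    new("ModularityMatrix", entries = B, degrees = k, totalWeight = m,
        group = integer(0))
  } else {
    group <- as.integer(group)
    Bg <- B[group, group, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    new("ModularityMatrix", entries = Bg, degrees = k, totalWeight = m,
        group = group)
  }
}

#' Modularity of a labeled partition
#'
#' `Q = sum_ij B_ij [c_i == c_j] / (2m)` evaluated on the original weighted
#' graph.
#'
#' @param graph an [AdjacencyGraph-class].
#' @param labels integer community label per node.
#' @return Scalar modularity.
#' @export
modularityScore <- function(graph, labels) {
  A <- graph@weights
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m <= 0) stop("graph has no edges")
  B <- A - outer(k, k) / (2 * m)
  same <- outer(labels, labels, "==")
  sum(B[same]) / (2 * m)
}

# Kernighan-Lin fine-tuning of a bisection (part of the leading-eigenvector
# method): in each pass every vertex is flipped exactly once in best-gain
# order -- accepting interim losses -- and the best intermediate state of the
# pass is kept; passes repeat while they improve s' Bg s.
.klRefine <- function(Bg, s, maxPasses = 50L) {
  n <- nrow(Bg)
  d <- diag(Bg)
  val <- drop(crossprod(s, Bg %*% s))
  for (pass in seq_len(maxPasses)) {
    cur <- s
    g <- as.vector(Bg %*% cur)
    curVal <- val
    free <- rep(TRUE, n)
    bestS <- s; bestVal <- val
    for (step in seq_len(n)) {
      gains <- -4 * cur * g + 4 * d
      gains[!free] <- -Inf
      i <- which.max(gains)
      curVal <- curVal + gains[i]
      g <- g - 2 * cur[i] * Bg[, i]
      cur[i] <- -cur[i]
      free[i] <- FALSE
      if (curVal > bestVal + 1e-12) { bestVal <- curVal; bestS <- cur }
    }
    if (bestVal <= val + 1e-12) break
    s <- bestS; val <- bestVal
  }
  s
}

# Recursive spectral bisection on the (generalized) modularity matrix.
# Returns an integer label vector over 1..n.
.spectralPartition <- function(A, tol = 1e-9) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(A) / 2
  if (m <= 0) return(rep(1L, n))
  B <- A - outer(k, k) / (2 * m)
  labels <- integer(n)
  nextLab <- 0L
  recurse <- function(nodes) {
    if (length(nodes) == 1L) {
      nextLab <<- nextLab + 1L
      labels[nodes] <<- nextLab
      return(invisible())
    }
    Bg <- B[nodes, nodes, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    e <- eigen(Bg, symmetric = TRUE)
    if (e$values[1L] <= tol) {           # no positive leading eigenvalue
      nextLab <<- nextLab + 1L
      labels[nodes] <<- nextLab
      return(invisible())
    }
    s <- ifelse(e$vectors[, 1L] >= 0, 1, -1)
    s <- .klRefine(Bg, s)
    dQ <- drop(crossprod(s, Bg %*% s)) / (4 * m)
    if (dQ <= tol || all(s == s[1L])) {  # split does not help
      nextLab <<- nextLab + 1L
      labels[nodes] <<- nextLab
      return(invisible())
    }
    recurse(nodes[s > 0])
    recurse(nodes[s < 0])
  }
  recurse(seq_len(n))
  labels
}

.relabelContiguous <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

.coassignment <- function(L) {
  # L: n x R label matrix -> fraction of runs assigning each pair together
  n <- nrow(L); R <- ncol(L)
  C <- matrix(0, n, n)
  for (r in seq_len(R)) C <- C + outer(L[, r], L[, r], "==")
  C / R
}

#' Detect communities by modularity maximization with consensus
#'
#' Recursive leading-eigenvector bisection of the modularity matrix: at each
#' stage the subgraph is split by the signs of the leading eigenvector of its
#' generalized modularity matrix (followed by a single-vertex fine-tuning
#' sweep), and a subgraph is left undivided when the leading eigenvalue or the
#' modularity contribution of the best split is non-positive. A consensus
#' wrapper repeats detection `consensusRuns` times under a small seeded
#' multiplicative weight jitter, thresholds the co-assignment matrix at 0.5,
#' and re-clusters the thresholded matrix until all runs agree.
#'
#' @param graph an [AdjacencyGraph-class] with positive total weight.
#' @param consensusRuns number of jittered detection runs per consensus cycle
#'   (1 = single deterministic run, no jitter).
#' @param seed RNG seed for the jitter.
#' @param jitter half-width of the uniform multiplicative weight jitter.
#' @param tol eigenvalue / modularity-gain positivity tolerance.
#' @param maxCycles maximum consensus cycles.
#' @return An [EnsembleAssignment-class] over the graph's nodes.
#' @export
detectCommunities <- function(graph, consensusRuns = 20L, seed = 1L,
                              jitter = 0.01, tol = 1e-9, maxCycles = 20L) {
  stopifnot(is(graph, "AdjacencyGraph"))
  if (consensusRuns < 1L) stop("consensusRuns must be >= 1")
  A0 <- graph@weights
  n <- nrow(A0)
  if (sum(A0) <= 0) stop("graph has no edges")
  set.seed(seed)
  A <- A0
  labels <- NULL
  for (cycle in seq_len(maxCycles)) {
    if (consensusRuns == 1L) {
      labels <- .spectralPartition(A, tol)
      break
    }
    L <- matrix(0L, n, consensusRuns)
    for (r in seq_len(consensusRuns)) {
      U <- matrix(0, n, n)
      U[upper.tri(U)] <- stats::runif(n * (n - 1) / 2, -jitter, jitter)
      U <- U + t(U)
      L[, r] <- .spectralPartition(A * (1 + U), tol)
    }
    C <- .coassignment(L)
    if (all(C < 1e-9 | C > 1 - 1e-9)) {   # binary-stable: all runs agree
      labels <- L[, 1L]
      break
    }
    A <- C * (C > 0.5)
    diag(A) <- 0
    if (sum(A) <= 0) { labels <- seq_len(n); break }
  }
  if (is.null(labels)) labels <- L[, 1L]   # last cycle's majority structure
  labels <- .relabelContiguous(labels)
  new("EnsembleAssignment", labels = labels,
      nEnsembles = max(labels), modularityQ = modularityScore(graph, labels),
      order = integer(0), excluded = graph@excluded)
}

#' Detect neuronal ensembles in a raster
#'
#' Convenience wrapper chaining [correlationDistance()], [fuzzyKnnGraph()]
#' and [detectCommunities()]. Zero-variance neurons are excluded from graph
#' construction and carry `NA` labels in the result.
#'
#' @param raster a [Raster-class].
#' @param nNeighbors fuzzy-graph neighborhood size.
#' @param consensusRuns,seed,... passed to [detectCommunities()].
#' @return An [EnsembleAssignment-class] over all raster neurons.
#' @export
detectEnsembles <- function(raster, nNeighbors = 10L, consensusRuns = 20L,
                            seed = 1L, ...) {
  d <- correlationDistance(raster)
  g <- fuzzyKnnGraph(d, nNeighbors)
  asg <- detectCommunities(g, consensusRuns, seed, ...)
  keep <- attr(d, "neurons")
  labels <- rep(NA_integer_, nNeurons(raster))
  labels[keep] <- asg@labels
  new("EnsembleAssignment", labels = labels, nEnsembles = asg@nEnsembles,
      modularityQ = asg@modularityQ, order = integer(0),
      excluded = attr(d, "excluded"))
}

#' Sort a raster by detected ensembles
#'
#' Groups neuron rows by community and orders the communities by the first
#' frame at which any member is active. Neurons without a label (excluded
#' zero-variance rows) are appended last, unlabeled.
#'
#' @param raster a [Raster-class].
#' @param assignment an [EnsembleAssignment-class] over the raster's neurons.
#' @return A list with `raster` (the sorted [Raster-class]), `permutation`
#'   (row order applied, so `sorted = original[permutation, ]`), and
#'   `communityOrder` (community ids by first activation).
#' @export
sortRaster <- function(raster, assignment) {
  stopifnot(is(raster, "Raster"), is(assignment, "EnsembleAssignment"))
  if (length(assignment@labels) != nNeurons(raster))
    stop("assignment covers ", length(assignment@labels),
         " neurons but raster has ", nNeurons(raster))
  a <- activityMatrix(raster)
  firstActive <- apply(a, 1L, function(x) {
    w <- which(x == 1L)
    if (length(w)) w[1L] else Inf
  })
  lab <- assignment@labels
  comFirst <- vapply(seq_len(assignment@nEnsembles),
                     function(g) min(firstActive[which(lab == g)], Inf),
                     numeric(1))
  communityOrder <- order(comFirst)
  rank <- match(lab, communityOrder)       # NA stays NA
  perm <- order(rank, seq_along(lab), na.last = TRUE)
  list(raster = subRaster(raster, perm), permutation = perm,
       communityOrder = as.integer(communityOrder))
}

#' Low-dimensional embedding of activity or population vectors
#'
#' Visualization-only coordinates obtained by spectral embedding of the same
#' fuzzy nearest-neighbor graph the ensemble detection uses: the eigenvectors
#' of the smallest non-trivial eigenvalues of the symmetric normalized graph
#' Laplacian, with signs fixed deterministically and the layout rescaled so
#' the smallest non-zero point separation equals `minDist`. No downstream
#' stage consumes these coordinates.
#'
#' @param vectors matrix of row vectors to embed (e.g. activity vectors), or
#'   a [Raster-class] whose rows are embedded.
#' @param nNeighbors fuzzy-graph neighborhood size.
#' @param nComponents output dimensionality (2 or 3).
#' @param minDist minimum point separation of the layout (default 0.1).
#' @param seed accepted for interface stability; the embedding is
#'   deterministic.
#' @return Numeric matrix, one row of coordinates per input vector.
#' @export
embedVectors <- function(vectors, nNeighbors = 10L, nComponents = 2L,
                         minDist = 0.1, seed = 1L) {
  if (is(vectors, "Raster")) vectors <- activityMatrix(vectors)
  vectors <- as.matrix(vectors)
  if (!nComponents %in% c(2L, 3L)) stop("nComponents must be 2 or 3")
  if (nrow(vectors) < nNeighbors + 1L)
    stop("need at least nNeighbors + 1 vectors")
  v <- apply(vectors, 1L, stats::var)
  if (any(v == 0)) stop("constant vectors cannot be embedded (zero variance)")
  r <- stats::cor(t(vectors))
  D <- 1 - r; D[D < 0] <- 0; diag(D) <- 0
  g <- fuzzyKnnGraph(D, nNeighbors)
  W <- g@weights
  deg <- rowSums(W)
  deg[deg == 0] <- 1
  S <- diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  L <- diag(nrow(W)) - S
  e <- eigen(L, symmetric = TRUE)
  n <- nrow(W)
  idx <- seq(n - 1L, by = -1L, length.out = nComponents)
  coords <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(coords))) {     # deterministic sign convention
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  pd <- stats::dist(coords)
  minNz <- suppressWarnings(min(pd[pd > 0]))
  if (is.finite(minNz) && minNz > 0) coords <- coords * (minDist / minNz)
  colnames(coords) <- paste0("dim", seq_len(nComponents))
  coords
}
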