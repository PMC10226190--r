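# Independent brute-force oracles for the PDC and graph-metric tests.
# These deliberately share no code with the package implementation:
# literal formula transcriptions with plain loops.

# PDC by direct per-frequency evaluation: Abar = I - sum_l A_l e^{-i2pifl/fs},
# entry-by-entry column normalization with explicit loops.
oracle_pdc <- function(coeffs, fs, freqs) {
  n <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  out <- array(NA_real_, c(length(freqs), n, n))
  for (k in seq_along(freqs)) {
    Abar <- matrix(0i, n, n)
    for (i in 1:n) for (j in 1:n) {
      a <- 0i
      for (l in 1:p) a <- a + coeffs[i, j, l] * exp(-1i * 2 * pi * freqs[k] * l / fs)
      Abar[i, j] <- (if (i == j) 1 else 0) - a
    }
    for (j in 1:n) {
      norm_j <- 0
      for (i in 1:n) norm_j <- norm_j + Mod(Abar[i, j])^2
      for (i in 1:n) out[k, i, j] <- Mod(Abar[i, j]) / sqrt(norm_j)
    }
  }
  out
}

# all-pairs shortest path lengths of a binary digraph (row = target
# convention: B[i, j] = 1 means edge j -> i) by Floyd-Warshall
oracle_spl <- function(B) {
  n <- nrow(B)
  d <- matrix(Inf, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j && B[i, j] > 0) d[j, i] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(B) {
  n <- nrow(B)
  if (n < 2) return(0)
  d <- oracle_spl(B)
  s <- 0
  for (i in 1:n) for (j in 1:n) if (i != j && is.finite(d[i, j]))
    s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracle_degrees <- function(B) {
  n <- nrow(B)
  ind <- outd <- numeric(n)
  for (i in 1:n) for (j in 1:n) if (B[i, j] > 0) {
    ind[i] <- ind[i] + 1; outd[j] <- outd[j] + 1
  }
  list(in_degree = ind, out_degree = outd, total = ind + outd)
}

oracle_strength <- function(W) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in 1:n) for (j in 1:n) s[i] <- s[i] + W[i, j] + W[j, i]
  s
}

oracle_clustering <- function(B) {
  n <- nrow(B)
  U <- (B + t(B)) > 0
  vapply(1:n, function(i) {
    nb <- which(U[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in nb) for (b in nb) if (a < b && U[a, b]) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, 0)
}

oracle_local_efficiency <- function(B) {
  n <- nrow(B)
  U <- (B + t(B)) > 0
  vapply(1:n, function(i) {
    nb <- which(U[i, ])
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(B[nb, nb, drop = FALSE])
  }, 0)
}

# Newman modularity of a given partition on the undirected simple graph
# (sum over edge ends convention, L = 2 * undirected edge count)
oracle_modularity_q <- function(B, membership) {
  U <- ((B + t(B)) > 0) * 1
  L <- sum(U)
  if (L == 0) return(0)
  k <- rowSums(U)
  q <- 0
  n <- nrow(U)
  for (i in 1:n) for (j in 1:n)
    if (membership[i] == membership[j])
      q <- q + U[i, j] - k[i] * k[j] / L
  q / L
}

# random digraph adjacency (row = target), zero diagonal
random_digraph <- function(n, p_edge = 0.4) {
  B <- matrix(as.numeric(runif(n * n) < p_edge), n, n)
  diag(B) <- 0
  B
}

# wrap a 0/1 (or weighted) matrix as the package's adjacency class without
# going through thresholding
as_adjacency <- function(W) {
  structure(list(weighted = W, binary = (W > 0) * 1,
                 p_kept = NA_real_, n_edges = sum(W > 0)),
            class = "adjacency_pair")
}

# univariate stationary AR variance by spectral integration (closed-form
# check for the simulator): var = sigma2 * mean over the unit circle of
# |1/A(e^{-iw})|^2
oracle_ar_variance <- function(a, sigma2 = 1, ngrid = 8192) {
  w <- 2 * pi * (seq_len(ngrid) - 1) / ngrid
  A <- 1 - vapply(w, function(x) sum(a * exp(-1i * x * seq_along(a))), 0i)
  sigma2 * mean(1 / Mod(A)^2)
}
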