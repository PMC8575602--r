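# Independent brute-force homology oracle: Betti numbers of the subcomplex
# at scale eps via ranks of dense GF(2) boundary matrices. No persistence
# pairing involved.

gf2_rank <- function(A) {
  if (is.null(dim(A)) || nrow(A) == 0 || ncol(A) == 0) return(0L)
  A <- A %% 2
  m <- nrow(A)
  rank <- 0L
  for (col in seq_len(ncol(A))) {
    if (rank == m) break
    rows <- (rank + 1L):m
    piv <- rows[A[rows, col] == 1][1]
    if (is.na(piv)) next
    rank <- rank + 1L
    if (piv != rank) { tmp <- A[rank, ]; A[rank, ] <- A[piv, ]; A[piv, ] <- tmp }
    ones <- setdiff(which(A[, col] == 1), rank)
    if (length(ones))
      A[ones, ] <- (A[ones, , drop = FALSE] +
                      matrix(A[rank, ], length(ones), ncol(A), byrow = TRUE)) %% 2
  }
  rank
}

# Dense boundary matrix from dim-d simplices (cols) to dim-(d-1) (rows),
# built by string-keyed facet lookup, independent of the package internals.
dense_boundary <- function(rows_vm, cols_vm) {
  if (ncol(cols_vm) == 0 || ncol(rows_vm) == 0)
    return(matrix(0L, ncol(rows_vm), ncol(cols_vm)))
  rkey <- apply(rows_vm, 2, paste, collapse = "-")
  B <- matrix(0L, ncol(rows_vm), ncol(cols_vm))
  for (j in seq_len(ncol(cols_vm))) {
    v <- cols_vm[, j]
    for (r in seq_along(v)) {
      i <- match(paste(v[-r], collapse = "-"), rkey)
      stopifnot(!is.na(i))
      B[i, j] <- 1L
    }
  }
  B
}

# beta_k(eps) for k = 0..kmax of a filtered_complex, by rank-nullity on the
# subcomplex with filtration value <= eps.
betti_oracle <- function(fc, eps, kmax = 2) {
  vm <- list(); nv <- integer(fc$max_dim + 1)
  for (d in 0:fc$max_dim) {
    keep <- fc$values[[d + 1]] <= eps + 1e-12
    vm[[d + 1]] <- fc$simplices[[d + 1]][, keep, drop = FALSE]
    nv[d + 1] <- sum(keep)
  }
  vapply(0:kmax, function(k) {
    rk_k <- if (k >= 1) gf2_rank(dense_boundary(vm[[k]], vm[[k + 1]])) else 0L
    rk_k1 <- if (k + 1 <= fc$max_dim)
      gf2_rank(dense_boundary(vm[[k + 1]], vm[[k + 2]])) else 0L
    nv[k + 1] - rk_k - rk_k1
  }, numeric(1))
}

# Random symmetric weight matrix in [0, 1] with zero diagonal.
rand_weights <- function(M, seed) {
  set.seed(seed)
  W <- matrix(0, M, M)
  W[upper.tri(W)] <- runif(M * (M - 1) / 2)
  W + t(W)
}
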