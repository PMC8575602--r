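# Cached vertex-subset enumerations, keyed by (n_vertices, size).
.combo_cache <- new.env(parent = emptyenv())
combos <- function(M, k) {
  key <- sprintf("%d_%d", M, k)
  if (is.null(.combo_cache[[key]]))
    .combo_cache[[key]] <- combn(M, k)
  .combo_cache[[key]]
}

#' Vietoris-Rips filtered complex from a weight matrix
#'
#' Enumerates every vertex subset of size up to `max_dim + 1` of the complete
#' graph and assigns it the maximum pairwise weight among its vertices
#' (vertices enter at 0). Weights are expected to be normalized
#' dissimilarities in \[0, 1\] with zero diagonal, as produced by
#' [to_filtration()].
#'
#' @param weights a normalized `connectivity_matrix`, or a plain symmetric
#'   numeric matrix with zero diagonal.
#' @param max_dim maximum simplex dimension (default 3, so that voids and the
#'   Euler cross-check through dimension 3 are computable).
#' @param cap refuse to build complexes with more simplices than this
#'   (default 2e6).
#' @return object of class `filtered_complex`: lists `simplices` (per
#'   dimension, a (k+1) x n_k matrix of vertex indices sorted ascending) and
#'   `values` (per dimension, filtration values), plus `n_vertices`,
#'   `max_dim`, `eps_max`.
#' @export
vietoris_rips <- function(weights, max_dim = 3, cap = 2e6) {
  normalized <- TRUE
  if (inherits(weights, "connectivity_matrix")) {
    if (!weights$normalized)
      stop("connectivity matrix must be normalized first; see to_filtration()")
    W <- weights$values
  } else {
    W <- as.matrix(weights)
    if (max(abs(W - t(W))) > 1e-9 || any(diag(W) != 0))
      stop("weights must be symmetric with zero diagonal")
    normalized <- all(W >= 0 & W <= 1)
  }
  M <- nrow(W)
  max_dim <- min(max_dim, M - 1)
  total <- sum(choose(M, seq_len(max_dim + 1)))
  if (total > cap)
    stop(sprintf(paste0("complex would have %g simplices (cap %g); threshold",
                        " the weights or reduce channels/max_dim"), total, cap))
  simplices <- vector("list", max_dim + 1)
  values <- vector("list", max_dim + 1)
  simplices[[1]] <- matrix(seq_len(M), nrow = 1)
  values[[1]] <- numeric(M)
  for (d in seq_len(max_dim)) {
    Vm <- combos(M, d + 1)
    pr <- combos(d + 1, 2)
    val <- rep(-Inf, ncol(Vm))
    for (p in seq_len(ncol(pr))) {
      a <- Vm[pr[1, p], ]; b <- Vm[pr[2, p], ]
      val <- pmax(val, W[cbind(a, b)])
    }
    simplices[[d + 1]] <- Vm
    values[[d + 1]] <- val
  }
  structure(list(simplices = simplices, values = values,
                 n_vertices = M, max_dim = max_dim,
                 eps_max = if (normalized) 1 else max(W)),
            class = "filtered_complex")
}

#' Assemble a filtered complex from explicit simplices
#'
#' Mainly for fixtures and tests: build a `filtered_complex` from a list of
#' vertex tuples with filtration values. Face closure is not completed
#' automatically; [persistence()] validates it.
#'
#' @param simplices list of integer vectors (vertex tuples).
#' @param values numeric filtration values, one per simplex.
#' @param n_vertices total vertex count (default: max vertex index).
#' @param eps_max maximal filtration scale (default: max value).
#' @return a `filtered_complex`.
#' @export
filtered_complex <- function(simplices, values,
                             n_vertices = max(unlist(simplices)),
                             eps_max = max(values)) {
  stopifnot(length(simplices) == length(values))
  dims <- lengths(simplices) - 1L
  max_dim <- max(dims)
  sim <- vector("list", max_dim + 1)
  val <- vector("list", max_dim + 1)
  for (d in 0:max_dim) {
    idx <- which(dims == d)
    sim[[d + 1]] <- if (length(idx))
      vapply(simplices[idx], function(v) sort(as.integer(v)), integer(d + 1))
    else matrix(integer(0), nrow = d + 1)
    if (d == 0) sim[[1]] <- matrix(as.integer(sim[[1]]), nrow = 1)
    val[[d + 1]] <- as.numeric(values[idx])
  }
  structure(list(simplices = sim, values = val, n_vertices = n_vertices,
                 max_dim = max_dim, eps_max = eps_max),
            class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  n <- vapply(x$simplices, ncol, 1L)
  cat(sprintf("Filtered complex: %d vertices, dims 0-%d, simplex counts (%s)\n",
              x$n_vertices, x$max_dim, paste(n, collapse = ", ")))
  invisible(x)
}

#' Total simplex count of a filtered complex
#' @param complex a `filtered_complex`.
#' @return integer count over all dimensions.
#' @export
n_simplices <- function(complex) sum(vapply(complex$simplices, ncol, 1L))

# Flatten a filtered_complex into filtration order (value, dim, lex) and
# compute the boundary matrix in compressed-column layout (1-based facet
# indices per column, unsorted; the reduction sorts them).
build_boundary <- function(fc) {
  B <- fc$n_vertices + 1
  nd <- vapply(fc$simplices, ncol, 1L)
  offset <- c(0, cumsum(nd))
  n <- sum(nd)
  dims <- rep(0:fc$max_dim, nd)
  vals <- unlist(fc$values, use.names = FALSE)
  lexcode <- numeric(n)                     # big-endian tuple code: lex order
  codes <- vector("list", fc$max_dim + 1)   # little-endian code for matching
  for (d in 0:fc$max_dim) {
    Vm <- fc$simplices[[d + 1]]
    if (!ncol(Vm)) { codes[[d + 1]] <- numeric(0); next }
    rows <- (offset[d + 1] + 1):(offset[d + 2])
    lexcode[rows] <- colSums(Vm * B^(d:0))
    codes[[d + 1]] <- colSums(Vm * B^(0:d))
  }
  ord <- order(vals, dims, lexcode)
  rnk <- integer(n); rnk[ord] <- seq_len(n)
  sizes <- integer(n)
  sizes[rnk] <- ifelse(dims == 0, 0L, dims + 1L)
  colptr <- c(0L, cumsum(sizes))
  entries <- integer(colptr[n + 1])
  for (d in seq_len(fc$max_dim)) {
    Vm <- fc$simplices[[d + 1]]
    if (!ncol(Vm)) next
    vals_d <- fc$values[[d + 1]]
    facR <- matrix(0L, d + 1, ncol(Vm))
    for (r in seq_len(d + 1)) {
      sub <- Vm[-r, , drop = FALSE]
      fcode <- colSums(sub * B^(0:(d - 1)))
      idx <- match(fcode, codes[[d]])
      if (anyNA(idx))
        stop("complex is not face-closed: a facet of a dim-", d,
             " simplex is missing")
      if (any(fc$values[[d]][idx] > vals_d + 1e-12))
        stop("filtration violates face ordering: a facet enters after its coface")
      facR[r, ] <- rnk[offset[d] + idx]
    }
    cols_global <- rnk[(offset[d + 1] + 1):(offset[d + 2])]
    pos <- rep(colptr[cols_global], each = d + 1) + seq_len(d + 1)
    entries[pos] <- as.vector(facR)
  }
  list(entries = entries, colptr = colptr, dims = dims[ord],
       values = vals[ord])
}

#' Persistence barcode of a filtered complex
#'
#' Standard boundary-matrix reduction over the two-element field, with
#' simplices totally ordered by (filtration value, dimension, lexicographic
#' vertex tuple) and the clearing optimization. Essential classes (alive at
#' the maximal scale) get `death = Inf`.
#'
#' @param complex a face-closed `filtered_complex`.
#' @return object of class `barcode_set`: a data.frame with columns
#'   `dimension`, `birth`, `death`, carrying attribute `eps_max`.
#' @export
persistence <- function(complex) {
  bd <- build_boundary(complex)
  res <- reduce_boundary_z2(bd$entries, bd$colptr, as.integer(bd$dims))
  pairs <- res$pairs
  bars <- data.frame(
    dimension = c(bd$dims[pairs[, 1]], bd$dims[res$essential]),
    birth = c(bd$values[pairs[, 1]], bd$values[res$essential]),
    death = c(bd$values[pairs[, 2]], rep(Inf, length(res$essential))))
  bars <- bars[order(bars$dimension, bars$birth, bars$death), ]
  rownames(bars) <- NULL
  structure(bars, eps_max = complex$eps_max, class = c("barcode_set",
                                                       "data.frame"))
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("Barcode: %d bars (%d essential), eps_max = %g\n",
              nrow(x), sum(is.infinite(x$death)), attr(x, "eps_max")))
  for (d in sort(unique(x$dimension))) {
    sub <- x[x$dimension == d, ]
    cat(sprintf("  dim %d: %d bars, %d of positive length\n", d, nrow(sub),
                sum(sub$death - sub$birth > 0)))
  }
  invisible(x)
}

#' Betti curves from a barcode
#'
#' `beta_k(eps)` = number of dimension-`k` bars with `birth <= eps < death`
#' (half-open convention; essential bars count for every `eps >= birth`).
#'
#' @param barcode a `barcode_set`.
#' @param grid numeric vector of filtration values.
#' @param max_dim highest dimension column to return (default 3).
#' @return integer matrix, `length(grid)` rows, columns `beta0`, `beta1`, ...
#' @export
betti_curves <- function(barcode, grid, max_dim = 3) {
  out <- matrix(0L, length(grid), max_dim + 1,
                dimnames = list(NULL, paste0("beta", 0:max_dim)))
  for (d in 0:max_dim) {
    sub <- barcode[barcode$dimension == d, ]
    if (!nrow(sub)) next
    for (g in seq_along(grid))
      out[g, d + 1] <- sum(sub$birth <= grid[g] & grid[g] < sub$death)
  }
  out
}

#' Euler characteristic and Euler entropy curves
#'
#' `chi(eps)` is the alternating sum of simplex counts at scale `eps`; the
#' Euler entropy is `S(eps) = ln |chi(eps)|`, with `-Inf` recorded where
#' `chi = 0`. The curve's transition point (negative peak of S) is attached.
#'
#' @param complex a `filtered_complex`.
#' @param grid filtration values at which to evaluate; default the sorted
#'   unique filtration values of the complex (every event is a grid point).
#' @param rule transition-point rule, see [phase_transition_point()].
#' @return object of class `euler_curve`: data.frame with columns `epsilon`,
#'   `chi`, `entropy`; attribute `transition_point`.
#' @export
euler_curve <- function(complex, grid = NULL,
                        rule = c("global-min", "first-zero")) {
  rule <- match.arg(rule)
  allv <- unlist(complex$values, use.names = FALSE)
  if (is.null(grid)) grid <- sort(unique(allv))
  chi <- integer(length(grid))
  for (d in 0:complex$max_dim) {
    v <- sort(complex$values[[d + 1]])
    if (!length(v)) next
    nk <- findInterval(grid + 1e-12, v)
    chi <- chi + (-1L)^d * nk
  }
  S <- ifelse(chi == 0, -Inf, log(abs(chi)))
  out <- structure(data.frame(epsilon = grid, chi = chi, entropy = S),
                   class = c("euler_curve", "data.frame"))
  attr(out, "transition_point") <- phase_transition_point(out, rule = rule)
  out
}

#' @export
print.euler_curve <- function(x, ...) {
  tp <- attr(x, "transition_point")
  cat(sprintf("Euler curve on %d grid points: chi in [%d, %d], transition at %s\n",
              nrow(x), min(x$chi), max(x$chi),
              if (is.na(tp)) "none" else format(tp)))
  invisible(x)
}

#' Topological phase-transition point of an Euler-entropy curve
#'
#' The scale at which the Euler entropy `S = ln |chi|` attains its negative
#' peak. Under the default `"global-min"` rule this is the smallest grid
#' value attaining the minimum of S (a `-Inf` from `chi = 0` always wins, so
#' ties resolve to the first zero crossing of chi); `NA` when S never drops
#' below its initial value (no negative peak). The `"first-zero"` rule takes
#' the first scale where chi reaches or crosses zero and `NA` if it never
#' does.
#'
#' @param curve an `euler_curve`.
#' @param rule `"global-min"` (default) or `"first-zero"`.
#' @return the transition scale, or `NA` if there is none.
#' @export
phase_transition_point <- function(curve, rule = c("global-min", "first-zero")) {
  rule <- match.arg(rule)
  chi <- curve$chi; S <- curve$entropy; grid <- curve$epsilon
  if (!length(grid)) return(NA_real_)
  if (rule == "first-zero") {
    hit <- which(chi == 0 | c(FALSE, chi[-1] * chi[-length(chi)] < 0))
    return(if (length(hit)) grid[hit[1]] else NA_real_)
  }
  m <- min(S)
  if (m >= S[1]) return(NA_real_)
  grid[which(S == m)[1]]
}
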