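#' Analytic signal via the FFT
#'
#' Real signal plus `j` times its Hilbert transform, computed by one-sided
#' spectrum doubling.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

#' Instantaneous phase of every channel of an epoch
#'
#' Four-quadrant angle of the analytic signal, channel by channel. The first
#' and last 10% of samples are flagged as edge-affected by the Hilbert
#' transform's implicit periodicity; they are retained but maskable
#' downstream.
#'
#' @param epoch channels x samples numeric matrix, assumed band-limited.
#' @param fs sampling rate in Hz.
#' @return object of class `phase_matrix`: list with `phases` (radians in
#'   (-pi, pi\]), `fs`, and logical vector `edge` marking edge-affected
#'   samples.
#' @export
instantaneous_phase <- function(epoch, fs) {
  epoch <- as.matrix(epoch)
  if (ncol(epoch) < 64) stop("epoch must have at least 64 samples")
  zero <- which(apply(epoch, 1, function(r) all(r == 0)))
  if (length(zero))
    stop(sprintf("phase undefined for all-zero channel(s): %s",
                 paste(zero, collapse = ", ")))
  phases <- t(apply(epoch, 1, function(r) Arg(analytic_signal(r))))
  n <- ncol(epoch)
  k <- floor(0.1 * n)
  edge <- rep(FALSE, n)
  if (k > 0) edge[c(seq_len(k), (n - k + 1):n)] <- TRUE
  structure(list(phases = phases, fs = fs, edge = edge),
            class = "phase_matrix")
}

#' Connectivity matrix container
#'
#' @param values symmetric M x M numeric matrix with zero diagonal.
#' @param kind `"C"` (phase-locking) or `"D"` (standardized distance).
#' @param normalized logical: entries rescaled to \[0, 1\] and ready to be
#'   used as filtration weights.
#' @param channel_labels optional labels.
#' @param band optional band label recorded as metadata.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("C", "D"),
                                normalized = FALSE, channel_labels = NULL,
                                band = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  dimnames(values) <- NULL
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (kind == "C" && (min(values) < -1e-9 || max(values) > 1 + 1e-9))
    stop("C-kind entries must lie in [0, 1]")
  structure(list(values = values, kind = kind, normalized = normalized,
                 channel_labels = channel_labels, band = band),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("%s-matrix (%d channels%s): off-diagonal range [%.3f, %.3f]\n",
              x$kind, nrow(x$values),
              if (x$normalized) ", filtration-ready" else "",
              min(off), max(off)))
  invisible(x)
}

#' Phase-locking value matrix (C-matrix)
#'
#' `C[p, q] = | mean_n exp(j (phi_p(n) - phi_q(n))) |` for `p != q`, and 0 on
#' the diagonal. 1 means perfect phase locking, values near 0 mean
#' independence.
#'
#' @param phases a `phase_matrix` from [instantaneous_phase()].
#' @param trim_edges drop the edge-affected samples before averaging
#'   (default `FALSE`: all samples are used).
#' @return a `connectivity_matrix` of kind `"C"`.
#' @export
plv_matrix <- function(phases, trim_edges = FALSE) {
  phi <- phases$phases
  if (nrow(phi) < 2) stop("need at least 2 channels")
  if (trim_edges) phi <- phi[, !phases$edge, drop = FALSE]
  Z <- exp(1i * phi)
  C <- Mod(Z %*% Conj(t(Z))) / ncol(phi)
  C <- pmin(pmax(C, 0), 1)
  diag(C) <- 0
  connectivity_matrix(C, kind = "C")
}

#' Standardized squared Euclidean distance matrix (D-matrix)
#'
#' `d(r, t) = sum_k ((r_k - t_k) / s_k)^2`, where `s_k` is the sample
#' standard deviation across all channels at sample position `k`.
#'
#' @param epoch channels x samples numeric matrix.
#' @param squared keep the squared form (default, as defined above); `FALSE`
#'   takes the square root. The two variants order Vietoris-Rips simplices
#'   identically after min-max normalization, but normalized values differ
#'   nonlinearly.
#' @return a `connectivity_matrix` of kind `"D"`.
#' @export
distance_matrix <- function(epoch, squared = TRUE) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 2) stop("need at least 2 channels")
  s <- apply(epoch, 2, sd)
  bad <- which(s == 0)
  if (length(bad))
    stop(sprintf("zero cross-channel standard deviation at sample(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  X <- sweep(epoch, 2, s, "/")
  D <- as.matrix(stats::dist(X))^2
  if (!squared) D <- sqrt(D)
  connectivity_matrix(D, kind = "D")
}

#' Convert a connectivity matrix to filtration weights
#'
#' C-kind: `w = 1 - C`, so strongly locked pairs get small weights and enter
#' the filtration early. D-kind: min-max normalization of the off-diagonal
#' entries to \[0, 1\]. The diagonal stays 0.
#'
#' @param matrix a `connectivity_matrix`.
#' @return a normalized `connectivity_matrix` usable by [vietoris_rips()].
#' @export
to_filtration <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  V <- matrix$values
  off <- upper.tri(V) | lower.tri(V)
  if (matrix$kind == "C") {
    W <- 1 - V
  } else {
    lo <- min(V[off]); hi <- max(V[off])
    if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
      warning("degenerate D-matrix (all off-diagonals equal): uniform weights 0.5")
      W <- V; W[off] <- 0.5
    } else {
      W <- (V - lo) / (hi - lo)
    }
  }
  diag(W) <- 0
  out <- matrix
  out$values <- W
  out$normalized <- TRUE
  out
}
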