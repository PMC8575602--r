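#' Persistent entropy of a barcode
#'
#' Shannon entropy of the normalized bar-length distribution:
#' `p_i = (y_i - x_i) / L`, `L = sum(y_i - x_i)`, `H = -sum p_i log p_i`.
#' Essential bars are truncated at the maximal filtration scale before
#' lengths are taken (dropping them would discard the largest-scale
#' structure); zero-length bars are dropped.
#'
#' Two rescalings are attached: `H_hat = H / log(l_max)` with `l_max` the
#' longest bar, computed exactly as defined even though `l_max <= 1` on a
#' normalized filtration makes the denominator non-positive (so `H_hat` can
#' be negative or undefined at `l_max = 1`); and `H_alt = H / log(n_bars)`,
#' a normalization to \[0, 1\] that is well defined on normalized
#' filtrations and is the default classifier feature downstream.
#'
#' @param barcode a `barcode_set` from [persistence()].
#' @param dims dimensions pooled into the barcode group (default `0:2`).
#' @param log_base logarithm base (default natural log; classification by
#'   thresholding is base-invariant).
#' @param eps_max truncation scale for essential bars; default the barcode's
#'   `eps_max` attribute.
#' @return object of class `pe_feature`: list with `H`, `H_hat`, `H_alt`,
#'   `n_bars`, `l_max`, `dims_used`, `log_base`.
#' @export
persistent_entropy <- function(barcode, dims = 0:2, log_base = exp(1),
                               eps_max = attr(barcode, "eps_max")) {
  stopifnot(is.data.frame(barcode))
  sub <- barcode[barcode$dimension %in% dims, , drop = FALSE]
  death <- sub$death
  if (is.null(eps_max)) eps_max <- max(death[is.finite(death)], sub$birth, 1)
  death[is.infinite(death)] <- eps_max
  len <- death - sub$birth
  len <- len[len > 1e-12]
  if (!length(len))
    stop("no positive-length bars in the requested dimensions")
  logb <- function(x) log(x) / log(log_base)
  L <- sum(len)
  p <- len / L
  H <- -sum(p * logb(p))
  l_max <- max(len)
  n <- length(len)
  H_hat <- if (abs(logb(l_max)) < 1e-12) NA_real_ else H / logb(l_max)
  H_alt <- if (n > 1) H / logb(n) else 0
  structure(list(H = H, H_hat = H_hat, H_alt = H_alt, n_bars = n,
                 l_max = l_max, dims_used = dims, log_base = log_base),
            class = "pe_feature")
}

#' @export
print.pe_feature <- function(x, ...) {
  cat(sprintf(paste0("Persistent entropy (dims %s, base %.4g): H = %.4f, ",
                     "H_hat = %s, H_alt = %.4f (%d bars, l_max = %.4f)\n"),
              paste(x$dims_used, collapse = ","), x$log_base, x$H,
              if (is.na(x$H_hat)) "undefined (l_max = 1)"
              else sprintf("%.4f", x$H_hat),
              x$H_alt, x$n_bars, x$l_max))
  invisible(x)
}

#' Rescaled persistent entropy
#'
#' `H_hat = H / log(l_max)`, with `l_max` the longest bar of the considered
#' barcode group. When `l_max = 1` the rescaling is undefined and the
#' alternative normalization `H_alt = H / log(n_bars)` is returned with a
#' warning.
#'
#' @param feature a `pe_feature` from [persistent_entropy()], or a
#'   `barcode_set` (forwarded through [persistent_entropy()]).
#' @param ... passed to [persistent_entropy()] when `feature` is a barcode.
#' @return the rescaled entropy (a number).
#' @export
rescaled_entropy <- function(feature, ...) {
  if (inherits(feature, "barcode_set")) feature <- persistent_entropy(feature, ...)
  stopifnot(inherits(feature, "pe_feature"))
  if (is.na(feature$H_hat)) {
    warning("l_max = 1 makes H / log(l_max) undefined; returning H_alt")
    return(feature$H_alt)
  }
  feature$H_hat
}
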