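# Shared toy fixtures, built in code.

hollow_triangle <- function(w = 0.3)
  filtered_complex(list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3)),
                   c(0, 0, 0, w, w, w), eps_max = 1)

tetra_boundary <- function(w = 0.2)
  filtered_complex(c(as.list(1:4),
                     combn(4, 2, simplify = FALSE),
                     combn(4, 3, simplify = FALSE)),
                   c(rep(0, 4), rep(w, 6), rep(w, 4)), eps_max = 1)

# 6-cycle with edge weights 0.1..0.6 and all chords at 0.9.
hexagon_weights <- function() {
  W <- matrix(0.9, 6, 6); diag(W) <- 0
  e <- cbind(1:6, c(2:6, 1))
  W[e] <- seq(0.1, 0.6, by = 0.1)
  W[e[, 2:1]] <- seq(0.1, 0.6, by = 0.1)
  W
}

# Small fast session config for pipeline-level tests.
small_config <- function(...) {
  session_config(n_channels = 10, n_rsd_trials = 8, n_gst_trials = 8,
                 stimulus_s = 3, cluster_channels = 1:5, ...)
}

barcode_of <- function(dimension, birth, death, eps_max = 1)
  structure(data.frame(dimension = dimension, birth = birth, death = death),
            eps_max = eps_max, class = c("barcode_set", "data.frame"))
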