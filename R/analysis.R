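#' Compare per-condition phase-transition points
#'
#' Compares the median transition scale of the two conditions: `"GST_first"`
#' when the GST median is strictly smaller, `"RSD_first"` when strictly
#' larger, `"tie"` otherwise (or when a condition has no defined transition).
#'
#' @param eps_star numeric vector of per-trial transition points (may contain
#'   `NA`).
#' @param labels per-trial condition labels (`"GST"` / `"RSD"`).
#' @return one of `"GST_first"`, `"RSD_first"`, `"tie"`.
#' @export
transition_comparison <- function(eps_star, labels) {
  stopifnot(length(eps_star) == length(labels))
  g <- eps_star[labels == "GST" & !is.na(eps_star)]
  r <- eps_star[labels == "RSD" & !is.na(eps_star)]
  if (!length(g) || !length(r)) {
    warning("a condition has no defined transition point; returning tie")
    return("tie")
  }
  mg <- median(g); mr <- median(r)
  if (mg < mr) "GST_first" else if (mg > mr) "RSD_first" else "tie"
}

# Best training-accuracy threshold for rule `v > thr => GST` (gst_high) or
# `v < thr => GST` (gst_low). Candidates: below min, midpoints, above max;
# ties resolve to the smallest candidate.
best_threshold <- function(values, labels, direction) {
  u <- sort(unique(values))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(th) {
    pred <- if (direction == "gst_high") ifelse(values > th, "GST", "RSD")
            else ifelse(values < th, "GST", "RSD")
    mean(pred == labels)
  }, numeric(1))
  cand[which.max(acc)]
}

#' Leave-one-trial-out distinguishing rate
#'
#' The condition-discrimination procedure: for each held-out trial a
#' threshold on the persistent-entropy feature is chosen on the remaining
#' trials to maximize training accuracy, with a fixed direction
#' (`"gst_high"`: GST predicted above threshold, used for C-matrix features;
#' `"gst_low"`: below, used for D-matrix features); the rate is the held-out
#' accuracy. Balanced accuracy (mean of per-class rates) is attached for the
#' unequal 30/10 design.
#'
#' @param values per-trial feature values.
#' @param labels per-trial condition labels (`"GST"` / `"RSD"`), both
#'   conditions with at least 2 trials.
#' @param direction threshold direction, see above.
#' @return the held-out accuracy in \[0, 1\], with attribute `balanced`.
#' @export
distinguishing_rate <- function(values, labels,
                                direction = c("gst_high", "gst_low")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  if (any(table(factor(labels, levels = c("GST", "RSD"))) < 2))
    stop("need at least 2 trials per condition")
  n <- length(values)
  pred <- character(n)
  for (i in seq_len(n)) {
    th <- best_threshold(values[-i], labels[-i], direction)
    pred[i] <- if (direction == "gst_high") {
      if (values[i] > th) "GST" else "RSD"
    } else {
      if (values[i] < th) "GST" else "RSD"
    }
  }
  correct <- pred == labels
  rate <- mean(correct)
  bal <- mean(c(mean(correct[labels == "GST"]), mean(correct[labels == "RSD"])))
  structure(rate, balanced = bal)
}

# Per-trial topological features for one (band, kind) cell.
trial_features <- function(epochs, kind, dims = 0:2, log_base = exp(1),
                           squared = TRUE, trim_edges = FALSE,
                           transition_rule = "global-min") {
  n_trials <- dim(epochs$data)[3]
  res <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ep <- epochs$data[, , i]
    cm <- if (kind == "C") {
      plv_matrix(instantaneous_phase(ep, epochs$fs), trim_edges = trim_edges)
    } else {
      distance_matrix(ep, squared = squared)
    }
    w <- to_filtration(cm)
    fc <- vietoris_rips(w)
    bc <- persistence(fc)
    pe <- persistent_entropy(bc, dims = dims, log_base = log_base)
    ec <- euler_curve(fc, rule = transition_rule)
    pe_dim <- vapply(0:2, function(d) {
      tryCatch(persistent_entropy(bc, dims = d, log_base = log_base)$H,
               error = function(e) NA_real_)
    }, numeric(1))
    res[[i]] <- data.frame(
      trial = i, condition = epochs$condition_labels[i],
      band = if (!is.null(epochs$band)) epochs$band$name else NA_character_,
      matrix_kind = kind, dims = paste(dims, collapse = ","),
      H = pe$H, H_hat = pe$H_hat, H_alt = pe$H_alt,
      H_dim0 = pe_dim[1], H_dim1 = pe_dim[2], H_dim2 = pe_dim[3],
      n_bars = pe$n_bars, l_max = pe$l_max,
      transition = attr(ec, "transition_point"))
  }
  do.call(rbind, res)
}

#' Full topological discrimination analysis of one session
#'
#' Runs the whole pipeline on a recording for each requested (band, matrix
#' kind) cell: band-limited baseline-corrected epochs, per-trial phase-locking
#' (C) or standardized-distance (D) connectivity, Vietoris-Rips filtration,
#' persistence barcode, persistent-entropy features, Euler-curve transition
#' points; then the per-cell leave-one-trial-out distinguishing rate, the
#' persistent-entropy direction between conditions, and the transition-point
#' ordering.
#'
#' @param recording an [eeg_recording()] with condition markers.
#' @param bands character vector of canonical band names, or a list of
#'   [band_spec()] objects (default `"alpha"`).
#' @param kinds connectivity kinds to analyse, subset of `c("C", "D")`.
#' @param target_fs processing rate (default 250 Hz).
#' @param window,baseline epoch and baseline windows, see [segment_epochs()].
#' @param feature which persistent-entropy variant feeds the classifier:
#'   `"H_alt"` (default, `H / log(n_bars)`), `"H"`, or `"H_hat"`.
#' @param dims homology dimensions pooled into the barcode group.
#' @param squared use the squared standardized distance (default) for D.
#' @param trim_edges drop Hilbert edge-affected samples from the PLV average.
#' @param transition_rule rule for [phase_transition_point()].
#' @param subject_id optional identifier carried into the results.
#' @return object of class `eeg_tda`: list with `features` (per-trial
#'   feature table), `summary` (one row per band x kind: distinguishing
#'   rate, balanced rate, PE direction, rank-test p-value, transition order),
#'   and the call parameters. Methods: `print`, `summary`, `plot`.
#' @examples
#' cfg <- session_config(n_rsd_trials = 4, n_gst_trials = 4, stimulus_s = 3,
#'                       n_channels = 8, seed = 7)
#' fit <- eeg_tda(generate_session(cfg), bands = "alpha", kinds = "C")
#' fit
#' @export
eeg_tda <- function(recording, bands = "alpha", kinds = c("C", "D"),
                    target_fs = 250, window = c(0, 2), baseline = c(-1, 0),
                    feature = c("H_alt", "H", "H_hat"), dims = 0:2,
                    squared = TRUE, trim_edges = FALSE,
                    transition_rule = c("global-min", "first-zero"),
                    subject_id = NA_character_) {
  feature <- match.arg(feature)
  transition_rule <- match.arg(transition_rule)
  if (is.character(bands)) bands <- eeg_bands(bands)
  if (inherits(bands, "band_spec")) bands <- list(bands)
  kinds <- match.arg(kinds, c("C", "D"), several.ok = TRUE)
  rec <- bandpass(recording, band_spec("whole", 1, 45))
  if (target_fs != rec$fs) rec <- downsample(rec, target_fs)
  feats <- list()
  summ <- list()
  for (b in seq_along(bands)) {
    band <- bands[[b]]
    banded <- bandpass(rec, band)
    epochs <- segment_epochs(banded, window = window, baseline = baseline,
                             band = band)
    for (kind in kinds) {
      ft <- trial_features(epochs, kind, dims = dims,
                           squared = squared, trim_edges = trim_edges,
                           transition_rule = transition_rule)
      v <- ft[[feature]]
      lab <- ft$condition
      rate <- distinguishing_rate(v, lab,
                                  direction = if (kind == "C") "gst_high"
                                              else "gst_low")
      med_g <- median(v[lab == "GST"]); med_r <- median(v[lab == "RSD"])
      dir <- if (med_g > med_r) "GST>RSD" else if (med_g < med_r) "GST<RSD"
             else "mixed"
      pval <- tryCatch(
        wilcox.test(v[lab == "GST"], v[lab == "RSD"], exact = FALSE)$p.value,
        error = function(e) NA_real_)
      feats[[length(feats) + 1]] <- ft
      summ[[length(summ) + 1]] <- data.frame(
        band = band$name, matrix_kind = kind,
        distinguishing_rate = as.numeric(rate),
        balanced_rate = attr(rate, "balanced"),
        pe_direction = dir, p_value = pval,
        transition_order = transition_comparison(ft$transition, lab))
    }
  }
  structure(list(subject_id = subject_id,
                 features = do.call(rbind, feats),
                 summary = do.call(rbind, summ),
                 feature = feature, bands = bands, kinds = kinds,
                 window = window, target_fs = target_fs),
            class = "eeg_tda")
}

#' @export
print.eeg_tda <- function(x, ...) {
  cat("Topological EEG condition analysis")
  if (!is.na(x$subject_id)) cat(sprintf(" [subject %s]", x$subject_id))
  cat(sprintf("\n  classifier feature: %s, window %g-%g s @ %g Hz\n",
              x$feature, x$window[1], x$window[2], x$target_fs))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.eeg_tda <- function(object, ...) {
  cat(sprintf("Trials: %d (%s)\n", nrow(object$features) /
                max(1, nrow(object$summary)),
              paste(sprintf("%s x%d", names(table(object$features$condition)),
                            table(object$features$condition) /
                              max(1, nrow(object$summary))), collapse = ", ")))
  print(object$summary, row.names = FALSE, digits = 3)
  invisible(object$summary)
}

#' Plot method: persistent-entropy features per condition and band
#'
#' Strip chart of the classifier feature by condition for every band x kind
#' cell, with the per-trial transition points in a second panel.
#'
#' @param x an `eeg_tda` object.
#' @param ... ignored.
#' @export
plot.eeg_tda <- function(x, ...) {
  ft <- x$features
  cells <- unique(ft[, c("band", "matrix_kind")])
  op <- graphics::par(mfrow = c(1, nrow(cells)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(cells))) {
    sub <- ft[ft$band == cells$band[i] & ft$matrix_kind == cells$matrix_kind[i], ]
    graphics::stripchart(sub[[x$feature]] ~ factor(sub$condition),
                         vertical = TRUE, method = "jitter", pch = 19,
                         col = c("#2166AC", "#B2182B"),
                         ylab = x$feature,
                         main = sprintf("%s band, %s-matrix",
                                        cells$band[i], cells$matrix_kind[i]))
  }
  invisible(x)
}

#' Multi-subject synthetic study
#'
#' Simulates `n_subjects` independent sessions (one seed substream each) and
#' runs [eeg_tda()] on every one; the per-subject summaries are stacked.
#'
#' @param n_subjects number of simulated subjects.
#' @param config base [session_config()]; each subject gets a derived seed.
#' @param seed master seed for the study.
#' @param ... passed to [eeg_tda()].
#' @return data.frame, one row per subject x band x kind, with the
#'   `eeg_tda` summary columns plus `subject`.
#' @export
run_study <- function(n_subjects = 20, config = session_config(), seed = 1,
                      ...) {
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- substream_seed(seed, s, salt = 9L)
    fit <- eeg_tda(generate_session(cfg), subject_id = as.character(s), ...)
    out[[s]] <- cbind(subject = s, fit$summary)
  }
  do.call(rbind, out)
}

#' Run the full pipeline and write its feature table
#'
#' Simulation, preprocessing, connectivity, topology, features and the
#' per-cell discrimination summary in one call, with both output tables
#' written as tab-separated text. Deterministic given `config$seed`.
#'
#' @param config a [session_config()].
#' @param out_dir directory for `features.tsv`, `summary.tsv` and a
#'   `manifest.tsv` recording the configuration and package version.
#' @param ... passed to [eeg_tda()].
#' @return the `eeg_tda` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir, ...) {
  fit <- eeg_tda(generate_session(config), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(fit$features, file.path(out_dir, "features.tsv"))
  write_feature_table(fit$summary, file.path(out_dir, "summary.tsv"))
  cfg_flat <- vapply(config, function(x) paste(format(x), collapse = ","), "")
  manifest <- data.frame(key = c(names(cfg_flat), "package_version"),
                         value = c(unname(cfg_flat),
                                   as.character(utils::packageVersion("eegtda"))))
  write_feature_table(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(fit)
}
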