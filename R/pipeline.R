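#' Default pipeline configuration
#'
#' All tunables of the end-to-end run, with the canonical study settings:
#' 100 five-second segments per state at 512 Hz, four PCs, four clusters
#' with 50 k-means restarts, 1000 surrogates. The list round-trips through
#' YAML unchanged, so a config file can carry a full reproduction recipe.
#'
#' @param ... Named overrides of any default field.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    simulate = list(n_per_type = 100, duration = 5, fs = 512,
                    fs_int = NULL, burn_in = 2, seed = 1),
    preprocess = list(invert = FALSE, notch = NULL, window = 5),
    features = list(normalize = "own"),
    prototyping = list(n_components = 4, k = 4, n_init = 50, seed = 1),
    evaluation = list(surrogates = 1000, seed = 1)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @param cfg A `run_config`.
#' @return `read_config`: the restored `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full model-driven classification pipeline
#'
#' Simulates the labeled segment set, fits model-driven prototypes,
#' classifies (by default the same segments: the model self-classification
#' experiment), and evaluates against the generating labels with a
#' Markov-chain surrogate test. When `newdata` is supplied it is
#' classified instead of the simulated set (generalized classification).
#'
#' @param config A `run_config` from [default_config()].
#' @param newdata Optional `segment_set` with true labels to classify in
#'   place of the simulated set.
#' @param out_dir Optional directory; when set, predictions
#'   (predictions.csv), the prototype set (prototypes.json) and the report
#'   (report.json) are written there.
#' @return A `performance_report`; the fitted `state_prototypes` and the
#'   predictions are attached as attributes `prototypes` and
#'   `predictions`.
#' @examples
#' \donttest{
#' cfg <- default_config(simulate = list(n_per_type = 10),
#'                       evaluation = list(surrogates = 100))
#' rep <- run_pipeline(cfg)
#' rep$mean_sensitivity
#' }
#' @export
run_pipeline <- function(config = default_config(), newdata = NULL,
                         out_dir = NULL) {
  s <- config$simulate
  ss <- simulate_type_set(s$n_per_type, s$duration, s$fs, seed = s$seed,
                          fs_int = s$fs_int %||% s$fs,
                          burn_in = s$burn_in)
  p <- config$prototyping
  proto <- fit_prototypes(ss, n_components = p$n_components, k = p$k,
                          n_init = p$n_init, seed = p$seed)
  target <- if (is.null(newdata)) ss else newdata
  pred <- predict(proto, target, norm = config$features$normalize %||% "own")
  e <- config$evaluation
  report <- evaluate_predictions(pred, surrogates = e$surrogates,
                                 seed = e$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(pred, file.path(out_dir, "predictions.csv"))
    write_prototypes(proto, file.path(out_dir, "prototypes.json"))
    jsonlite::write_json(
      list(confusion = report$confusion,
           per_type_sensitivity = report$per_type_sensitivity,
           per_type_ppv = report$per_type_ppv,
           mean_sensitivity = report$mean_sensitivity,
           mean_ppv = report$mean_ppv,
           p_sensitivity = report$p_sensitivity,
           p_ppv = report$p_ppv,
           config = unclass(config)),
      file.path(out_dir, "report.json"), digits = NA, auto_unbox = TRUE,
      na = "null")
  }
  attr(report, "prototypes") <- proto
  attr(report, "predictions") <- pred
  report
}

#' Generate synthetic fixture datasets
#'
#' Programmatic test inputs emulating the study's data situations:
#' \describe{
#'   \item{concatenated_states}{one continuous recording cycling
#'     interictal -> preonset -> onset -> ictal (a stylized seizure
#'     traversal) with known per-segment labels.}
#'   \item{degenerate}{constant, pure-sinusoid and single-spike segments
#'     that exercise the documented warning/error paths.}
#'   \item{multi_subject}{three or more "subjects" with unequal state
#'     frequencies and jittered synaptic gains; the first subject lacks
#'     onset entirely (as in the rat recordings).}
#' }
#'
#' @param kind One of `"concatenated_states"`, `"degenerate"`,
#'   `"multi_subject"`.
#' @param seed Master seed.
#' @param n_cycles Traversal cycles for `concatenated_states` (each cycle
#'   contributes 4 five-second segments).
#' @param n_subjects Number of subjects for `multi_subject`.
#' @param fs Sampling rate.
#' @param out_dir Optional directory: signals are written as one-column
#'   text files with YAML sidecars plus label CSVs.
#' @return For `concatenated_states`, a list with `recording` and
#'   `labels`; for `degenerate`, a named list of `eeg_segment`s; for
#'   `multi_subject`, a list of per-subject lists with `segments` and
#'   `labels`.
#' @export
make_fixture <- function(kind = c("concatenated_states", "degenerate",
                                  "multi_subject"),
                         seed = 1, n_cycles = 20, n_subjects = 3, fs = 512,
                         out_dir = NULL) {
  kind <- match.arg(kind)
  cfgs <- wendling_state_configs()
  fx <- switch(kind,
    concatenated_states = {
      labels <- rep(rep(1:4, each = 1), n_cycles)
      segs <- lapply(seq_along(labels), function(i)
        simulate_wendling(cfgs[[labels[i]]], 5, fs, seed = seed + i))
      rec <- recording(unlist(lapply(segs, `[[`, "samples")), fs,
                       subject_id = "synthetic_traversal")
      list(recording = rec, labels = labels)
    },
    degenerate = {
      n <- 5 * fs
      set.seed(seed)
      list(constant = new_segment(rep(1, n), fs),
           sinusoid = new_segment(sin(2 * pi * 8 * seq_len(n) / fs), fs),
           spike = new_segment(c(rep(0, n - 1), 10)[sample(n)], fs))
    },
    multi_subject = {
      lapply(seq_len(n_subjects), function(j) {
        set.seed(seed + 1000 * j)
        weights <- stats::runif(4, 0.5, 2)
        if (j == 1) weights[3] <- 0          # first subject lacks onset
        n_seg <- pmax(0L, as.integer(round(12 * weights / sum(weights) * 4)))
        if (all(n_seg == 0)) n_seg[1] <- 1L
        labels <- rep(1:4, times = n_seg)
        segs <- lapply(seq_along(labels), function(i) {
          cfg <- cfgs[[labels[i]]]
          jit <- wendling_params(A = cfg$A * stats::runif(1, 0.9, 1.1),
                                 B = cfg$B * stats::runif(1, 0.9, 1.1),
                                 G = cfg$G * stats::runif(1, 0.9, 1.1))
          attr(jit, "label") <- labels[i]
          simulate_wendling(jit, 5, fs, seed = seed + 1000 * j + i)
        })
        list(segments = structure(segs, class = "segment_set",
                                  labels = labels),
             labels = labels, subject_id = paste0("synthetic_subject_", j))
      })
    })
  if (!is.null(out_dir)) write_fixture(fx, kind, out_dir)
  fx
}

write_fixture <- function(fx, kind, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(samples, fs, stem, subject) {
    sig <- file.path(out_dir, paste0(stem, ".txt"))
    writeLines(format(samples, digits = 10, trim = TRUE, scientific = FALSE),
               sig)
    yaml::write_yaml(list(fs = fs, subject_id = subject, channel_id = "ch1",
                          invert = FALSE), paste0(sig, ".yaml"))
  }
  if (kind == "concatenated_states") {
    write_one(fx$recording$samples, fx$recording$fs, "traversal",
              fx$recording$subject_id)
    utils::write.csv(data.frame(segment_index = seq_along(fx$labels),
                                label = fx$labels),
                     file.path(out_dir, "traversal_labels.csv"),
                     row.names = FALSE)
  } else if (kind == "degenerate") {
    for (nm in names(fx)) write_one(fx[[nm]]$samples, fx[[nm]]$fs, nm, nm)
  } else {
    for (sub in fx) {
      stem <- sub$subject_id
      write_one(unlist(lapply(sub$segments, `[[`, "samples")),
                sub$segments[[1]]$fs, stem, stem)
      utils::write.csv(data.frame(segment_index = seq_along(sub$labels),
                                  label = sub$labels),
                       file.path(out_dir, paste0(stem, "_labels.csv")),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Write a simulated segment set as delimited files plus manifest
#'
#' One one-column text file per segment and a `manifest.csv` with columns
#' segment_id, state_label, seed, fs, duration.
#'
#' @param segs A `segment_set`.
#' @param out_dir Output directory.
#' @param seed The master seed used to generate `segs` (recorded only).
#' @export
write_segments <- function(segs, out_dir, seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("segment_%04d", seq_along(segs))
  for (i in seq_along(segs))
    writeLines(format(segs[[i]]$samples, digits = 10, trim = TRUE,
                      scientific = FALSE),
               file.path(out_dir, paste0(ids[i], ".txt")))
  utils::write.csv(
    data.frame(segment_id = ids,
               state_label = segment_labels(segs),
               seed = if (is.na(seed)) NA else seed + seq_along(segs),
               fs = vapply(segs, `[[`, numeric(1), "fs"),
               duration = vapply(segs, function(s)
                 length(s$samples) / s$fs, numeric(1))),
    file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Write a feature matrix as CSV (plus normalization stats as JSON)
#' @param fm A `feature_matrix`.
#' @param path Output CSV; stats go to `<path>.stats.json` when the
#'   matrix is normalized.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(segment_id = seq_len(nrow(fm)), unclass(fm)[,],
                   check.names = FALSE)
  labs <- attr(fm, "labels")
  if (!all(is.na(labs))) df$true_label <- labs
  utils::write.csv(df, path, row.names = FALSE)
  ns <- attr(fm, "norm_stats")
  if (!is.null(ns))
    jsonlite::write_json(ns, paste0(path, ".stats.json"), digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV file.
#' @param dataset_id Identifier for the restored matrix.
#' @return A raw `feature_matrix` (labels restored when present).
#' @export
read_features <- function(path, dataset_id = "dataset") {
  df <- utils::read.csv(path, check.names = FALSE)
  labs <- if ("true_label" %in% names(df)) as.integer(df$true_label)
          else rep(NA_integer_, nrow(df))
  fm <- as.matrix(df[, feature_names()])
  structure(fm, class = c("feature_matrix", class(fm)),
            labels = labs, dataset_id = dataset_id, normalized = FALSE)
}
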