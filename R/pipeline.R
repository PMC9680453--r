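# End-to-end experiment harness: generate -> curate -> split -> extract ->
# train -> evaluate -> compare, from one configuration with full seed
# control. Every stage writes its artifacts under the output directory with
# the configuration echoed, and the subject-wise split is audited against
# leakage before any training starts.

#' Configuration of an end-to-end comparison experiment
#'
#' @param phantom a [phantom_config()]; its `n_subjects` and `seed` define the
#'   dataset stage.
#' @param fractions subject-wise split fractions (training, validation,
#'   testing).
#' @param backbone backbone name (see [backbone_spec()]).
#' @param backbone_weights `"random"` or `"pretrained"`.
#' @param variants model variants to compare (subset of
#'   `c("cnn", "2-lstm", "bi-lstm", "2-gru", "bi-gru")`).
#' @param epochs training epochs per variant.
#' @param time_steps sequence length (default 25).
#' @param seed master seed; the phantom, split, initialisation, shuffling and
#'   dropout streams are all derived from it, so a configuration reruns to an
#'   identical report.
#' @param output_dir directory for all artifacts.
#' @param violations optional violation plan forwarded to
#'   [generate_dataset()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(n_subjects = 60L),
                              fractions = c(training = 0.591, validation = 0.220,
                                            testing = 0.189),
                              backbone = "TinyTest",
                              backbone_weights = "random",
                              variants = MODEL_VARIANTS,
                              epochs = 15L,
                              time_steps = 25L,
                              seed = 1L,
                              output_dir = tempfile("saxlevel-exp"),
                              violations = NULL) {
  bad <- setdiff(variants, MODEL_VARIANTS)
  if (length(bad)) stopf("unknown model variant(s): %s", paste(bad, collapse = ", "))
  structure(list(phantom = phantom, fractions = fractions, backbone = backbone,
                 backbone_weights = backbone_weights, variants = variants,
                 epochs = as.integer(epochs), time_steps = as.integer(time_steps),
                 seed = as.integer(seed), output_dir = output_dir,
                 violations = violations),
            class = "experiment_config")
}

stage_msg <- function(verbose, fmt, ...) if (verbose) message(sprintf(fmt, ...))

# Extract features and build padded sequences for a set of per-sequence
# samples. Returns list(sequences, features_by_stack).
extract_stage <- function(samples, spec, time_steps, cache_dir = NULL) {
  lapply(samples, function(s) {
    feats <- extract_features(s$paths, spec, cache_dir = cache_dir)
    build_sequences(feats, s$ordinals, slice_index = s$slice_index,
                    time_steps = time_steps)
  })
}

# Flatten a list of feature sequences into per-image training data.
flatten_valid <- function(seqs) {
  x <- do.call(rbind, lapply(seqs, function(s) s$x[s$mask, , drop = FALSE]))
  y <- unlist(lapply(seqs, function(s) s$y[s$mask]))
  list(x = x, y = y)
}

#' Run the end-to-end model comparison experiment
#'
#' Executes all stages in order on a synthetic phantom dataset: dataset
#' generation, curation (exclusion rules), subject-wise splitting with a
#' leakage audit, frozen-backbone feature extraction, training of every
#' requested variant (batch size 32 for the per-image head, 2 for sequence
#' models), epoch selection on validation loss, and pooled evaluation on the
#' held-out test subjects. Artifacts (dataset, split, per-variant histories
#' and evaluation reports, and the comparison summary) are written under
#' `config$output_dir`. A rerun with an identical configuration reproduces
#' the report.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return Object of class `slice_comparison`: per-variant `slice_eval`
#'   reports and fits, the SOTD summary table, selected epochs, the split and
#'   the configuration echo.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  stage_msg(verbose, "generate: %d subjects -> %s", config$phantom$n_subjects, data_dir)
  manifest <- run_stage("generate",
    generate_dataset(config$phantom, data_dir, violations = config$violations))

  stage_msg(verbose, "curate")
  curated <- run_stage("curate", curate_dataset(data_dir))
  store <- run_stage("curate", load_label_store(file.path(data_dir, "labels.json")))

  stage_msg(verbose, "split: %d retained subjects", length(curated$retained))
  split_obj <- run_stage("split",
    split_subjects(curated$retained, config$fractions, seed = derive_seed(config$seed, 2)))
  jsonlite::write_json(list(assignment = as.list(split_obj$assignment),
                            fractions = as.list(split_obj$fractions), seed = split_obj$seed),
                       file.path(out, "split.json"), auto_unbox = TRUE, pretty = TRUE)
  parts <- split(names(split_obj$assignment), split_obj$assignment)
  # leakage audit: subject-wise disjointness is a hard invariant
  stopifnot(length(Reduce(intersect, parts[lengths(parts) > 0])) == 0 ||
              sum(lengths(parts) > 0) == 1)

  stage_msg(verbose, "extract: backbone %s", config$backbone)
  spec <- run_stage("extract",
    backbone_spec(config$backbone, weights = config$backbone_weights,
                  seed = derive_seed(config$seed, 3)))
  cache_dir <- file.path(out, "feature-cache")
  seqs <- lapply(parts, function(ids) run_stage("extract", {
    samples <- assemble_samples(data_dir, store, sort(ids), mode = "per-sequence")
    extract_stage(samples, spec, config$time_steps, cache_dir = cache_dir)
  }))
  flat <- lapply(seqs, flatten_valid)

  fits <- list(); reports <- list(); epochs_sel <- integer(0)
  for (v in config$variants) {
    stage_msg(verbose, "train: %s (%d epochs)", v, config$epochs)
    fit <- run_stage("train", {
      tseed <- derive_seed(config$seed, 10 + match(v, MODEL_VARIANTS))
      if (v == "cnn")
        fit_slice_model(flat$training, flat$validation, "cnn",
                        epochs = config$epochs, seed = tseed)
      else
        fit_slice_model(seqs$training, seqs$validation, v,
                        epochs = config$epochs, time_steps = config$time_steps,
                        seed = tseed)
    })
    utils::write.csv(fit$history, file.path(out, sprintf("history-%s.csv", v)),
                     row.names = FALSE)
    report <- run_stage("evaluate", evaluate_fit(fit, seqs$testing))
    fits[[v]] <- fit
    reports[[v]] <- report
    epochs_sel[v] <- fit$selected_epoch
    stage_msg(verbose, "evaluate: %s acc %.3f sotd %d", v, report$accuracy, report$sotd)
  }

  sotd_table <- data.frame(variant = names(reports),
                           accuracy = vapply(reports, function(r) r$accuracy, 0),
                           weighted_auc = vapply(reports, function(r) r$weighted_auc, 0),
                           macro_f1 = vapply(reports, function(r) mean(r$per_class$f1), 0),
                           sotd = vapply(reports, function(r) r$sotd, 0L),
                           merged_error = vapply(reports, function(r) r$merged$error_rate, 0),
                           selected_epoch = unname(epochs_sel),
                           row.names = NULL)
  result <- structure(list(reports = reports, fits = fits, summary = sotd_table,
                           split = split_obj, manifest = manifest,
                           backbone = spec$name,
                           config = config),
                      class = "slice_comparison")
  jsonlite::write_json(comparison_json(result), file.path(out, "comparison.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(utils::capture.output(print(result)), file.path(out, "comparison.txt"))
  result
}

comparison_json <- function(x) {
  list(backbone = x$backbone,
       seed = x$config$seed,
       n_subjects = x$config$phantom$n_subjects,
       split_sizes = as.list(x$split$sizes),
       variants = lapply(x$reports, function(r)
         list(accuracy = r$accuracy, weighted_auc = r$weighted_auc,
              sotd = r$sotd, merged_error_rate = r$merged$error_rate,
              per_class_f1 = setNames(as.list(r$per_class$f1), r$per_class$class),
              confusion = unname(r$cm))))
}

#' Evaluate a fitted classifier on a set of test sequences
#'
#' Predicts every valid slice of every test stack and pools them into one
#' evaluation report. Coverage is total by construction: each stack's valid
#' steps are all predicted.
#'
#' @param fit a `slice_fit`.
#' @param test_seqs list of `feature_sequence` objects.
#' @return A [evaluate_predictions()] report.
#' @export
evaluate_fit <- function(fit, test_seqs) {
  truth <- integer(0); pred <- integer(0); probs <- NULL
  for (s in test_seqs) {
    p <- predict_stack(fit, s)
    if (length(p$ordinals) != s$n)
      stopf("prediction coverage gap: expected %d valid slices, got %d",
            s$n, length(p$ordinals))
    truth <- c(truth, s$y[s$mask])
    pred <- c(pred, p$ordinals)
    probs <- rbind(probs, p$probs)
  }
  evaluate_predictions(truth, pred, probs)
}

#' @export
print.slice_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison on synthetic phantoms (backbone %s, %d subjects, seed %d)\n",
              x$backbone, x$config$phantom$n_subjects, x$config$seed))
  cat(sprintf("Split sizes: training %d / validation %d / testing %d\n\n",
              x$split$sizes[1], x$split$sizes[2], x$split$sizes[3]))
  tab <- x$summary
  for (col in c("accuracy", "weighted_auc", "macro_f1", "merged_error"))
    tab[[col]] <- round(tab[[col]], digits)
  print(tab, row.names = FALSE)
  cat("\nSOTD by variant (lower is better):\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s %s %d\n", tab$variant[i],
                strrep("#", min(tab$sotd[i], 60L)), tab$sotd[i]))
  invisible(x)
}

#' Per-subject textual prediction report
#'
#' One line per valid slice with slice index, ground truth, prediction and a
#' correctness flag.
#'
#' @param fit a `slice_fit`.
#' @param sequence the subject/phase `feature_sequence` to report.
#' @param subject,phase identifiers used in the header line.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_subject_report <- function(fit, sequence, subject = "?", phase = "?") {
  stopifnot(inherits(sequence, "feature_sequence"))
  if (all(is.na(sequence$y[sequence$mask])))
    stopf("subject %s has no labels; cannot render a report", subject)
  p <- predict_stack(fit, sequence)
  truth <- ordinal_to_label(sequence$y[sequence$mask])
  lines <- c(sprintf("subject %s, phase %s (%d slices, apex to base)", subject, phase,
                     sequence$n),
             vapply(seq_len(sequence$n), function(i) {
               ok <- truth[i] == p$labels[i]
               sprintf("  slice %2d  (%s)  (P = %s)  %s", i - 1L,
                       toupper(truth[i]), toupper(p$labels[i]),
                       if (ok) "correct" else "INCORRECT")
             }, ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
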