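# Dataset curation: exclusion rules, intensity rescaling, subject-wise
# splitting, label persistence and sample assembly.
#
# On-disk layout: <root>/<subject>/<phase>/<index>.png with a labels.json
# sidecar. A slice identifier is the (subject, phase, slice_index) key; the
# slice index is the leading integer of the file name, so "3.png" and
# "3.dup.png" collide on index 3 (a duplicate identifier).

parse_slice_index <- function(files) {
  idx <- suppressWarnings(as.integer(sub("^([0-9]+)\\..*$", "\\1", files)))
  if (anyNA(idx))
    stopf("unparseable slice file name(s): %s",
          paste(files[is.na(idx)], collapse = ", "))
  idx
}

read_phase_indices <- function(subject_dir) {
  phases <- sort(list.dirs(subject_dir, recursive = FALSE, full.names = FALSE))
  if (!length(phases)) stopf("no phase directories under %s", subject_dir)
  lapply(setNames(phases, phases), function(ph) {
    files <- sort(list.files(file.path(subject_dir, ph), pattern = "\\.png$"))
    parse_slice_index(files)
  })
}

#' Check one subject against the curation exclusion rules
#'
#' A subject is excluded when any of three violations is found:
#' `duplicate-identifier` (two image files map to the same
#' (phase, slice index) key), `inconsistent-phase-slice-count` (the phases of
#' one subject have different numbers of distinct slice indices), or
#' `non-contiguous-indices` (the sorted distinct indices of some phase are not
#' the consecutive integers 0..n-1, e.g. slice index 3 missing from a
#' 10-slice series). Unreadable directories raise an error, which is distinct
#' from a rule violation.
#'
#' @param subject_dir path to one subject's directory.
#' @return Character vector of violation tokens; empty when the subject is
#'   clean (and hence retained).
#' @export
validate_subject <- function(subject_dir) {
  if (!dir.exists(subject_dir)) stopf("subject directory not readable: %s", subject_dir)
  idx <- read_phase_indices(subject_dir)
  v <- character(0)
  if (any(vapply(idx, anyDuplicated, 1L) > 0L))
    v <- c(v, "duplicate-identifier")
  n_unique <- vapply(idx, function(i) length(unique(i)), 1L)
  if (length(unique(n_unique)) > 1L)
    v <- c(v, "inconsistent-phase-slice-count")
  noncontig <- vapply(idx, function(i) {
    u <- sort(unique(i))
    !identical(u, seq(0L, length(u) - 1L))
  }, TRUE)
  if (any(noncontig))
    v <- c(v, "non-contiguous-indices")
  v
}

#' Apply the exclusion rules to a whole dataset
#'
#' @param root dataset root directory (one subdirectory per subject).
#' @return List with `retained` (character vector of clean subject ids) and
#'   `excluded` (named list: subject id -> violation tokens).
#' @export
curate_dataset <- function(root) {
  subjects <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(subjects)) stopf("no subject directories under %s", root)
  violations <- lapply(setNames(subjects, subjects),
                       function(s) validate_subject(file.path(root, s)))
  keep <- vapply(violations, length, 1L) == 0L
  list(retained = subjects[keep], excluded = violations[!keep])
}

#' Rescale a raw image linearly to 8-bit range
#'
#' Linear min--max map to `[0, 255]`, rounded to the nearest integer. A
#' constant image (degenerate range) maps to all zeros.
#'
#' @param x non-empty numeric matrix.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
rescale_to_uint8 <- function(x) {
  if (!is.matrix(x) || length(x) == 0L) stopf("input must be a non-empty matrix")
  if (!is.numeric(x) || anyNA(x)) stopf("input must be numeric with no missing values")
  rng <- range(x)
  out <- if (rng[2] > rng[1]) round(255 * (x - rng[1]) / (rng[2] - rng[1])) else x * 0
  matrix(as.integer(out), nrow(x), ncol(x))
}

#' Subject-wise train/validation/test split
#'
#' Randomly partitions subject ids into training, validation and testing sets.
#' Partition sizes are the largest-remainder rounding of `fractions` (ties in
#' the remainders broken by partition order: training, validation, testing),
#' so the split is reproducible and exactly sized. The assignment is
#' subject-wise: a subject's images can never straddle partitions. The default
#' fractions reproduce the 59.1/22.0/18.9 percent study split, which on 974
#' subjects yields sizes 576/214/184.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param fractions numeric length-3 vector summing to 1 (tolerance 1e-6), in
#'   the order training, validation, testing.
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return Object of class `split_assignment`: list with `assignment` (named
#'   character vector id -> partition), `sizes`, `fractions`, `seed`.
#' @export
split_subjects <- function(subject_ids,
                           fractions = c(training = 0.591, validation = 0.220,
                                         testing = 0.189),
                           seed = 1L) {
  parts <- c("training", "validation", "testing")
  if (length(fractions) != 3L) stopf("fractions must have length 3")
  if (abs(sum(fractions) - 1) > 1e-6) stopf("fractions must sum to 1 (got %.7f)", sum(fractions))
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  if (anyDuplicated(subject_ids)) stopf("subject ids must be unique")
  n <- length(subject_ids)
  if (n < sum(fractions > 0))
    stopf("fewer subjects (%d) than partitions with nonzero fraction (%d)",
          n, sum(fractions > 0))
  target <- n * fractions
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(-(target - sizes))[seq_len(rem)]  # stable: ties keep partition order
    sizes[extra] <- sizes[extra] + 1
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(subject_ids))
  assignment <- setNames(rep(parts, times = sizes), shuffled)
  assignment <- assignment[subject_ids]  # original id order
  structure(list(assignment = assignment,
                 sizes = setNames(as.integer(sizes), parts),
                 fractions = setNames(as.numeric(fractions), parts),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Subject-wise split (seed ", x$seed, "):\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Save or load the label store sidecar
#'
#' The label store is the persisted mapping
#' (subject, phase, slice index) -> class token, stored as nested JSON keyed
#' subject, then phase, then slice index. Partial stores (labelling sessions
#' that can be resumed) are valid. `save_label_store` followed by
#' `load_label_store` is the identity on the mapping.
#'
#' @param store a data frame with columns `subject`, `phase`, `slice_index`,
#'   `label` (class tokens from [label_levels()]).
#' @param path file path of the JSON sidecar.
#' @return `load_label_store` returns the store data frame, rows ordered by
#'   subject, phase, slice index.
#' @export
save_label_store <- function(store, path) {
  stopifnot(is.data.frame(store),
            all(c("subject", "phase", "slice_index", "label") %in% names(store)))
  label_to_ordinal(store$label)  # validates tokens
  nested <- list()
  for (i in seq_len(nrow(store)))
    nested[[store$subject[i]]][[store$phase[i]]][[as.character(store$slice_index[i])]] <-
      store$label[i]
  jsonlite::write_json(nested, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_label_store
#' @export
load_label_store <- function(path) {
  if (!file.exists(path)) stopf("label store not found: %s", path)
  nested <- jsonlite::read_json(path)
  rows <- list()
  for (s in names(nested)) for (ph in names(nested[[s]])) {
    entries <- nested[[s]][[ph]]
    for (k in names(entries)) {
      tok <- entries[[k]]
      if (!is.character(tok) || length(tok) != 1L || !(tok %in% label_levels()))
        stopf("label store %s: unknown class token '%s' at %s/%s/%s",
              path, paste(format(tok), collapse = ","), s, ph, k)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, phase = ph, slice_index = as.integer(k), label = tok,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(), phase = character(),
                      slice_index = integer(), label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$subject, out$phase, out$slice_index), , drop = FALSE]
}

#' Assemble labelled samples from a curated dataset
#'
#' In `per-image` mode each labelled slice is one sample (the unit the
#' per-image baseline classifier trains on); in `per-sequence` mode each
#' (subject, phase) stack is one sample, i.e. exactly two samples per subject,
#' which is the unit the sequence models train on.
#'
#' @param root dataset root directory.
#' @param store label store data frame (see [load_label_store()]).
#' @param subjects subject ids to include (e.g. the retained set from
#'   [curate_dataset()]).
#' @param mode `"per-image"` or `"per-sequence"`.
#' @return `per-image`: data frame with one row per labelled slice (columns
#'   `subject`, `phase`, `slice_index`, `path`, `label`, `ordinal`).
#'   `per-sequence`: list with one element per (subject, phase), each a list
#'   with `subject`, `phase`, `paths` (ordered apex to base), `labels`,
#'   `ordinals`, `slice_index`.
#' @export
assemble_samples <- function(root, store, subjects,
                             mode = c("per-image", "per-sequence")) {
  mode <- match.arg(mode)
  rows <- list()
  for (s in subjects) {
    idx <- read_phase_indices(file.path(root, s))
    for (ph in names(idx)) {
      ord_idx <- sort(unique(idx[[ph]]))
      sl <- store[store$subject == s & store$phase == ph, , drop = FALSE]
      lab <- setNames(sl$label, as.character(sl$slice_index))
      missing <- setdiff(as.character(ord_idx), names(lab))
      if (length(missing))
        stopf("missing label for subject %s, phase %s, slice %s",
              s, ph, paste(missing, collapse = ", "))
      rows[[paste(s, ph)]] <- data.frame(
        subject = s, phase = ph, slice_index = ord_idx,
        path = file.path(root, s, ph, sprintf("%d.png", ord_idx)),
        label = unname(lab[as.character(ord_idx)]),
        stringsAsFactors = FALSE)
    }
  }
  flat <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  flat$ordinal <- label_to_ordinal(flat$label)
  if (mode == "per-image") return(flat)
  lapply(unname(rows), function(r)
    list(subject = r$subject[1], phase = r$phase[1], paths = r$path,
         labels = r$label, ordinals = label_to_ordinal(r$label),
         slice_index = r$slice_index))
}

#' Pick diastolic and systolic frames from a full cine series (stand-in)
#'
#' The curation core assumes the two phase frames per slice are already
#' chosen. For full cine input this helper selects frame 1 as diastole and,
#' as a stand-in proxy for minimal ventricular volume, the frame minimising
#' the sum of intensities above the image median (a blood-pool brightness
#' proxy) as systole. It is a documented heuristic, not a validated phase
#' detector.
#'
#' @param frames list of numeric matrices, one per cine frame of a slice.
#' @return List with `diastole` and `systole` frame indices.
#' @export
select_phase_frames <- function(frames) {
  stopifnot(length(frames) >= 2L)
  proxy <- vapply(frames, function(f) sum(f[f > stats::median(f)]), 0)
  list(diastole = 1L, systole = which.min(proxy))
}
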