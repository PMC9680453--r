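# Synthetic cardiac short-axis phantoms.
#
# The generator reproduces only the morphology that defines the five slice
# levels: presence/absence of the bright LV blood pool, papillary-muscle blobs
# inside the pool at the mid level, a larger basal ring, and an out-of-basal
# myocardial crescent with no pool. It makes no attempt at MRI physics.

#' Configuration for the synthetic phantom generator
#'
#' Geometry ranges are expressed as fractions of the image side so that the
#' same configuration scales with `image_size`. The defaults encode the study
#' conditions used throughout the package: stacks of 8--25 contiguous slices,
#' two cardiac phases (diastole, systole) sharing one label sequence, and a
#' systolic cavity contraction that makes systolic basal cavities overlap
#' diastolic apical/mid cavity sizes, so single slices are genuinely ambiguous
#' without sequence context.
#'
#' @param n_subjects number of subjects to generate.
#' @param image_size pixels per side of the square slice images.
#' @param slices_min,slices_max slice-count range per (subject, phase);
#'   must satisfy `1 <= slices_min <= slices_max <= 25`.
#' @param noise_sd standard deviation of the additive per-pixel Gaussian noise,
#'   in 8-bit intensity units.
#' @param cavity_frac named list of length-2 ranges (fractions of image side)
#'   for the diastolic blood-pool radius at the `ap`, `mid` and `bs` levels.
#' @param wall_frac range for myocardial wall thickness (fraction of side).
#' @param blob_frac range for papillary blob radius (fraction of side).
#' @param n_blobs_range integer range for the number of papillary blobs on mid
#'   slices.
#' @param systolic_scale range for the systolic cavity scale factor; must be
#'   strictly below 1 (systole < diastole).
#' @param crescent_arc_deg range (degrees) for the angular width of the
#'   out-of-basal myocardial crescent.
#' @param seed base random seed for the whole dataset.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_subjects = 20L,
                           image_size = 128L,
                           slices_min = 8L,
                           slices_max = 25L,
                           noise_sd = 6,
                           cavity_frac = list(ap = c(0.05, 0.08),
                                              mid = c(0.09, 0.13),
                                              bs = c(0.13, 0.17)),
                           wall_frac = c(0.04, 0.06),
                           blob_frac = c(0.015, 0.03),
                           n_blobs_range = c(1L, 3L),
                           systolic_scale = c(0.55, 0.80),
                           crescent_arc_deg = c(120, 220),
                           seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), image_size = as.integer(image_size),
              slices_min = as.integer(slices_min), slices_max = as.integer(slices_max),
              noise_sd = noise_sd, cavity_frac = cavity_frac, wall_frac = wall_frac,
              blob_frac = blob_frac, n_blobs_range = as.integer(n_blobs_range),
              systolic_scale = systolic_scale, crescent_arc_deg = crescent_arc_deg,
              seed = as.integer(seed))
  if (cfg$slices_min < 1L) stopf("slices_min must be >= 1")
  if (cfg$slices_max > 25L) stopf("slices_max must be <= 25 (sequence length bound)")
  if (cfg$slices_min > cfg$slices_max) stopf("slices_min must not exceed slices_max")
  if (any(cfg$systolic_scale >= 1)) stopf("systolic cavity scale must be < 1")
  if (any(unlist(cfg$cavity_frac) <= 0) || any(cfg$wall_frac <= 0) || any(cfg$blob_frac <= 0))
    stopf("all radii must be positive")
  # cavity + wall must fit inside the image with room for the centre offset
  max_outer <- max(unlist(cfg$cavity_frac)) + max(cfg$wall_frac)
  if (max_outer >= 0.5 - 0.06)
    stopf("geometry does not fit: cavity + wall fraction %.3f too large for the image", max_outer)
  if (cfg$noise_sd < 0) stopf("noise_sd must be non-negative")
  class(cfg) <- "phantom_config"
  cfg
}

# Sample a per-subject geometry draw from the configured ranges. All radii are
# in pixels; per-slice jitter is applied at render time.
sample_geometry <- function(cfg) {
  S <- cfg$image_size
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  n_blobs <- sample(seq(cfg$n_blobs_range[1], cfg$n_blobs_range[2]), 1)
  list(
    cx = 0.5 + stats::runif(1, -0.04, 0.04),
    cy = 0.5 + stats::runif(1, -0.04, 0.04),
    cavity = c(ap = runif1(cfg$cavity_frac$ap), mid = runif1(cfg$cavity_frac$mid),
               bs = runif1(cfg$cavity_frac$bs)) * S,
    wall = runif1(cfg$wall_frac) * S,
    blob_r = max(1.5, runif1(cfg$blob_frac) * S),
    n_blobs = n_blobs,
    blob_angle = stats::runif(n_blobs, 0, 2 * pi),
    blob_dist = stats::runif(n_blobs, 0.15, 0.55),
    systolic_scale = runif1(cfg$systolic_scale),
    crescent_arc = runif1(cfg$crescent_arc_deg) * pi / 180,
    crescent_rot = stats::runif(1, 0, 2 * pi)
  )
}

# intensity palette (8-bit); myocardium and papillary muscle are dark,
# the blood pool bright, background in between
PALETTE <- list(background = 90, myocardium = 35, pool = 225, blob = 45,
                texture_sd = 18)

smooth3 <- function(m) {
  # 3x3 box blur with replicated edges; cheap texture smoothing
  n <- nrow(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  (pad[1:n, 1:n] + pad[1:n, 2:(n + 1)] + pad[1:n, 3:(n + 2)] +
   pad[2:(n + 1), 1:n] + pad[2:(n + 1), 2:(n + 1)] + pad[2:(n + 1), 3:(n + 2)] +
   pad[3:(n + 2), 1:n] + pad[3:(n + 2), 2:(n + 1)] + pad[3:(n + 2), 3:(n + 2)]) / 9
}

#' Render one synthetic short-axis slice
#'
#' Draws the morphology that defines a slice level: `oap` is textured
#' background only; `ap` a dark myocardial annulus around a small bright blood
#' pool; `mid` additionally contains dark papillary blobs inside the pool;
#' `bs` a larger annulus with a bright pool and no blobs; `obs` a dark partial
#' annulus (crescent) with no enclosed pool. Systole shrinks the cavity by the
#' geometry's `systolic_scale` while the outer myocardial radius is kept, so
#' the wall thickens. The ground-truth region masks used to draw the slice are
#' attached as attributes `pool_mask`, `blob_mask` and `myo_mask` (a renderer
#' side channel for testing).
#'
#' @param level class token in `label_levels()` or ordinal 0..4.
#' @param phase `"diastole"` or `"systole"`.
#' @param geometry a geometry draw as produced internally from a
#'   [phantom_config()]; see Details in the package vignette.
#' @param image_size pixels per side.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed controlling texture and noise; identical inputs
#'   give bit-identical images.
#' @param jitter per-slice multiplicative jitter on the cavity radius.
#' @return Integer matrix in `[0, 255]` with mask attributes.
#' @export
render_slice <- function(level, phase = c("diastole", "systole"), geometry,
                         image_size = 128L, noise_sd = 6, seed = 1L,
                         jitter = 1.0) {
  phase <- match.arg(phase)
  if (is.numeric(level)) level <- ordinal_to_label(level)
  level <- match.arg(level, label_levels())
  S <- as.integer(image_size)
  g <- geometry
  cx <- g$cx * S; cy <- g$cy * S

  xs <- matrix(rep(seq_len(S), each = S), S, S)       # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)      # row index
  dx <- xs - cx; dy <- ys - cy
  dist <- sqrt(dx^2 + dy^2)

  pool <- matrix(FALSE, S, S); myo <- pool; blob <- pool

  if (level %in% c("ap", "mid", "bs")) {
    r_dia <- g$cavity[[level]] * jitter
    r_cav <- if (phase == "systole") r_dia * g$systolic_scale else r_dia
    r_out <- r_dia + g$wall
    if (r_out + max(abs(cx - S / 2), abs(cy - S / 2)) >= S / 2 - 1)
      stopf("geometry does not fit the %d px image: outer radius %.1f px", S, r_out)
    pool <- dist < r_cav
    myo <- dist < r_out & !pool
    if (level == "mid") {
      for (k in seq_len(g$n_blobs)) {
        bd <- g$blob_dist[k] * max(r_cav - g$blob_r - 1, 0)
        bx <- cx + bd * cos(g$blob_angle[k]); by <- cy + bd * sin(g$blob_angle[k])
        blob <- blob | (sqrt((xs - bx)^2 + (ys - by)^2) < g$blob_r & pool)
      }
    }
  } else if (level == "obs") {
    r_in <- g$cavity[["bs"]] * jitter
    r_out <- r_in + g$wall
    if (r_out >= S / 2 - 1)
      stopf("geometry does not fit the %d px image: crescent radius %.1f px", S, r_out)
    ang <- atan2(dy, dx)
    dang <- abs(((ang - g$crescent_rot + pi) %% (2 * pi)) - pi)
    myo <- dist >= r_in & dist < r_out & dang < g$crescent_arc / 2
  }

  img <- withr::with_seed(as.integer(seed), {
    tex <- smooth3(smooth3(matrix(stats::rnorm(S * S, 0, PALETTE$texture_sd), S, S)))
    base <- matrix(PALETTE$background, S, S) + tex
    base[myo] <- PALETTE$myocardium
    base[pool] <- PALETTE$pool
    base[blob] <- PALETTE$blob
    base + matrix(stats::rnorm(S * S, 0, noise_sd), S, S)
  })
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), S, S)
  attr(img, "pool_mask") <- pool & !blob
  attr(img, "blob_mask") <- blob
  attr(img, "myo_mask") <- myo
  attr(img, "level") <- level
  attr(img, "phase") <- phase
  img
}

# Draw a label sequence of length n: monotone oap* ap* mid* bs* obs* with the
# three in-ventricle levels always present, out-of-level runs at the ends
# present with nonzero probability.
sample_label_sequence <- function(n) {
  n_oap <- sample(0:2, 1, prob = c(0.30, 0.45, 0.25))
  n_obs <- sample(0:2, 1, prob = c(0.30, 0.45, 0.25))
  r <- n - n_oap - n_obs  # n >= 8 and at most 4 out-of-level slices => r >= 4
  cuts <- sort(sample(seq_len(r - 1), 2))
  counts <- c(n_oap, cuts[1], cuts[2] - cuts[1], r - cuts[2], n_obs)
  rep(label_levels(), times = counts)
}

#' Generate one phantom subject
#'
#' Draws a slice count uniformly in the configured range, a monotone
#' apex-to-base label sequence with at least three distinct classes present,
#' and one geometry per subject, then renders both cardiac phases from the
#' same label sequence.
#'
#' @param config a [phantom_config()].
#' @param subject_seed integer seed; identical `(config, subject_seed)` give
#'   identical subjects.
#' @param subject_id identifier string.
#' @return An object of class `phantom_subject`: list with `subject_id`,
#'   `labels` (tokens, apex to base), `stacks$diastole` / `stacks$systole`
#'   (lists of rendered slices) and the geometry draw.
#' @export
generate_subject <- function(config, subject_seed = 1L, subject_id = "S001") {
  stopifnot(inherits(config, "phantom_config"))
  drawn <- withr::with_seed(as.integer(subject_seed), {
    n <- sample(seq(config$slices_min, config$slices_max), 1)
    labels <- sample_label_sequence(n)
    geom <- sample_geometry(config)
    jit <- stats::runif(n, 0.95, 1.05)
    list(n = n, labels = labels, geom = geom, jit = jit)
  })
  stacks <- list()
  for (ph in c("diastole", "systole")) {
    pid <- if (ph == "diastole") 0L else 1L
    stacks[[ph]] <- lapply(seq_len(drawn$n), function(i) {
      render_slice(drawn$labels[i], ph, drawn$geom,
                   image_size = config$image_size, noise_sd = config$noise_sd,
                   seed = derive_seed(subject_seed, i, pid),
                   jitter = drawn$jit[i])
    })
  }
  structure(list(subject_id = subject_id, n_slices = drawn$n,
                 labels = drawn$labels, ordinals = label_to_ordinal(drawn$labels),
                 geometry = drawn$geom, stacks = stacks),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("Phantom subject %s: %d slices x 2 phases\n", x$subject_id, x$n_slices))
  cat("  labels (apex to base):", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes the on-disk layout consumed by the curation module:
#' `<out_dir>/<subject>/<phase>/<index>.png` (8-bit grayscale PNG), a
#' `labels.json` sidecar mapping subject/phase/slice index to class token, and
#' a `manifest.json` recording subjects, the corruption plan, a configuration
#' echo and the seed. An optional violation plan corrupts named subjects with
#' exactly one of the three curation-rule violations:
#' `"duplicate-identifier"` (a second file mapping to an existing slice
#' index), `"inconsistent-phase-slice-count"` (last systolic slice removed),
#' or `"non-contiguous-indices"` (a middle slice index removed from both
#' phases).
#'
#' @param config a [phantom_config()].
#' @param out_dir writable output directory (created if needed).
#' @param violations optional named character vector `subject_id -> kind`.
#' @return The manifest, invisibly (also written as JSON): list with
#'   `subjects`, `clean`, `corrupted`, `plan`, `direction`, `seed`.
#' @export
generate_dataset <- function(config, out_dir, violations = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  if (!is.null(violations)) {
    if (is.null(names(violations)) || any(!nzchar(names(violations))))
      stopf("violation plan must be a named vector: subject_id -> kind")
    unknown <- setdiff(names(violations), ids)
    if (length(unknown)) stopf("violation plan names unknown subject(s): %s",
                               paste(unknown, collapse = ", "))
    kinds <- c("duplicate-identifier", "inconsistent-phase-slice-count",
               "non-contiguous-indices")
    bad <- setdiff(unlist(violations), kinds)
    if (length(bad)) stopf("unknown violation kind(s): %s", paste(bad, collapse = ", "))
  }
  labels <- list()
  for (i in seq_along(ids)) {
    subj <- generate_subject(config, derive_seed(config$seed, i), ids[i])
    lab <- as.list(subj$labels); names(lab) <- as.character(seq_len(subj$n_slices) - 1L)
    labels[[ids[i]]] <- list(diastole = lab, systole = lab)
    for (ph in c("diastole", "systole")) {
      d <- file.path(out_dir, ids[i], ph)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(subj$n_slices))
        png::writePNG(subj$stacks[[ph]][[k]] / 255, file.path(d, sprintf("%d.png", k - 1L)))
    }
    if (!is.null(violations) && ids[i] %in% names(violations))
      plant_violation(file.path(out_dir, ids[i]), violations[[ids[i]]], subj$n_slices)
  }
  jsonlite::write_json(labels, file.path(out_dir, "labels.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- list(
    subjects = ids,
    clean = setdiff(ids, names(violations)),
    corrupted = if (is.null(violations)) character(0) else names(violations),
    plan = as.list(violations %||% setNames(character(0), character(0))),
    direction = "apex_to_base",
    shared_labels_across_phases = TRUE,
    config = config[setdiff(names(config), "cavity_frac")],
    cavity_frac = config$cavity_frac,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

plant_violation <- function(subject_dir, kind, n_slices) {
  mid_idx <- n_slices %/% 2L  # interior index: 0 < mid_idx < n-1 for n >= 3
  switch(kind,
    "duplicate-identifier" = {
      src <- file.path(subject_dir, "diastole", sprintf("%d.png", mid_idx))
      file.copy(src, file.path(subject_dir, "diastole", sprintf("%d.dup.png", mid_idx)))
    },
    "inconsistent-phase-slice-count" = {
      file.remove(file.path(subject_dir, "systole", sprintf("%d.png", n_slices - 1L)))
    },
    "non-contiguous-indices" = {
      for (ph in c("diastole", "systole"))
        file.remove(file.path(subject_dir, ph, sprintf("%d.png", mid_idx)))
    },
    stopf("unknown violation kind: %s", kind))
  invisible(NULL)
}
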