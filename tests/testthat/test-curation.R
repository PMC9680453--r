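test_that("each planted violation kind is detected exactly", {
  cfg <- small_config(n_subjects = 4, seed = 71)
  d <- withr::local_tempdir()
  plan <- c(S001 = "duplicate-identifier",
            S002 = "inconsistent-phase-slice-count",
            S003 = "non-contiguous-indices")
  generate_dataset(cfg, d, violations = plan)
  for (s in names(plan))
    expect_identical(validate_subject(file.path(d, s)), unname(plan[s]))
  expect_length(validate_subject(file.path(d, "S004")), 0)
  expect_error(validate_subject(file.path(d, "NOPE")), "not readable")
})

test_that("curation retains exactly the uncorrupted subjects", {
  cfg <- small_config(n_subjects = 6, seed = 81)
  d <- withr::local_tempdir()
  plan <- c(S002 = "duplicate-identifier", S005 = "non-contiguous-indices")
  generate_dataset(cfg, d, violations = plan)
  cur <- curate_dataset(d)
  expect_setequal(cur$retained, c("S001", "S003", "S004", "S006"))
  expect_setequal(names(cur$excluded), names(plan))
})

test_that("rescale_to_uint8 matches the affine oracle and handles edge cases", {
  x <- matrix(c(0, 200, 100, 400), 2, 2)
  expect_identical(rescale_to_uint8(x), matrix(c(0L, 128L, 64L, 255L), 2, 2))
  # oracle: round(255 * (x - min) / (max - min)) on random inputs
  for (s in 1:20) {
    m <- withr::with_seed(s, matrix(rnorm(30, 100, 50), 5, 6))
    got <- rescale_to_uint8(m)
    want <- round(255 * (m - min(m)) / (max(m) - min(m)))
    expect_equal(as.numeric(got), as.numeric(want))
    expect_true(all(got >= 0L & got <= 255L))
  }
  expect_identical(rescale_to_uint8(matrix(7, 3, 3)), matrix(0L, 3, 3))
  already <- matrix(as.numeric(c(0, 128, 255, 17)), 2, 2)
  expect_identical(rescale_to_uint8(already), matrix(as.integer(already), 2, 2))
  # idempotent on its own full-range output
  once <- rescale_to_uint8(matrix(c(3, 9, 4, 1), 2, 2))
  expect_identical(rescale_to_uint8(matrix(as.numeric(once), 2, 2)), once)
  expect_error(rescale_to_uint8(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("the study split fractions reproduce the published partition sizes", {
  ids <- sprintf("subj%04d", 1:974)
  sp <- split_subjects(ids, seed = 5)
  expect_identical(sp$sizes, c(training = 576L, validation = 214L, testing = 184L))
  expect_setequal(names(sp$assignment), ids)
})

test_that("splits are disjoint covering partitions for random sizes and seeds", {
  for (trial in 1:25) {
    n <- withr::with_seed(trial, sample(3:400, 1))
    ids <- sprintf("p%d", seq_len(n))
    sp <- split_subjects(ids, seed = trial)
    expect_identical(sum(sp$sizes), n)
    parts <- split(names(sp$assignment), sp$assignment)
    expect_length(Reduce(intersect, parts), 0)
    expect_setequal(unlist(parts), ids)
    # sizes are the largest-remainder rounding
    target <- n * sp$fractions
    expect_true(all(abs(sp$sizes - target) < 1))
  }
})

test_that("split is deterministic per seed and subject-wise by construction", {
  ids <- sprintf("s%d", 1:50)
  a <- split_subjects(ids, seed = 3)
  b <- split_subjects(ids, seed = 3)
  expect_identical(a$assignment, b$assignment)
  c <- split_subjects(ids, seed = 4)
  expect_false(identical(a$assignment, c$assignment))
  all_train <- split_subjects(ids, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$assignment == "training"))
  expect_error(split_subjects(ids, fractions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(split_subjects(c("a", "b"), fractions = c(0.4, 0.3, 0.3)),
               "fewer subjects")
})

test_that("label store round-trips losslessly and validates tokens", {
  store <- data.frame(subject = c("S1", "S1", "S2"),
                      phase = c("diastole", "systole", "diastole"),
                      slice_index = c(0L, 0L, 3L),
                      label = c("oap", "mid", "obs"),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  save_label_store(store, f)
  back <- load_label_store(f)
  expect_identical(back[order(back$subject, back$phase), ],
                   store[order(store$subject, store$phase), ],
                   ignore_attr = TRUE)
  expect_equal(nrow(back), 3)

  empty <- store[0, , drop = FALSE]
  f2 <- withr::local_tempfile(fileext = ".json")
  save_label_store(empty, f2)
  expect_equal(nrow(load_label_store(f2)), 0)

  writeLines('{"S1": {"diastole": {"0": "apex"}}}', f2)
  expect_error(load_label_store(f2), "unknown class token 'apex'")
})

test_that("sample assembly counts follow the per-image and per-sequence definitions", {
  cfg <- small_config(n_subjects = 3, seed = 91)
  d <- withr::local_tempdir()
  generate_dataset(cfg, d)
  store <- load_label_store(file.path(d, "labels.json"))
  cur <- curate_dataset(d)
  seqs <- assemble_samples(d, store, cur$retained, "per-sequence")
  expect_length(seqs, 2 * length(cur$retained))
  imgs <- assemble_samples(d, store, cur$retained, "per-image")
  expect_equal(nrow(imgs), nrow(store))
  expect_equal(nrow(imgs), sum(vapply(seqs, function(s) length(s$paths), 0L)))
  # a gap in the labels is reported with its coordinates
  store2 <- store[-1, ]
  missing <- store[1, ]
  expect_error(assemble_samples(d, store2, cur$retained, "per-image"),
               sprintf("subject %s, phase %s", missing$subject, missing$phase))
})

test_that("phase-frame selection stand-in prefers the dimmest-pool frame", {
  bright <- matrix(c(rep(0, 90), rep(250, 10)), 10, 10)
  dim_ <- matrix(c(rep(0, 97), rep(250, 3)), 10, 10)
  frames <- list(bright, bright, dim_, bright)
  sel <- select_phase_frames(frames)
  expect_equal(sel$diastole, 1L)
  expect_equal(sel$systole, 3L)
})
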