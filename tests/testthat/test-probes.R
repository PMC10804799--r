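test_that("segmentation covers the protein block in near-equal parts", {
  s <- segment_protein_columns(14L, 7L)
  expect_equal(s$size, rep(2L, 7))
  expect_equal(s$start[1], 1L)
  expect_equal(s$end[7], 14L)

  # 2554 = 7 * 364 + 6: six segments of 365, then one of 364
  s <- segment_protein_columns(2554L, 7L)
  expect_equal(s$size, c(rep(365L, 6), 364L))
  expect_equal(sum(s$size), 2554L)
  expect_true(all(diff(s$size) <= 0))
  expect_true(max(s$size) - min(s$size) <= 1L)
  # contiguous, non-overlapping cover
  expect_equal(s$start[-1], s$end[-7] + 1L)

  one <- segment_protein_columns(10L, 1L)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(1L, 10L))
  expect_error(segment_protein_columns(5L, 7L), "cannot divide")
})

test_that("probe receptor selection applies a strict CC threshold", {
  rep <- structure(list(per_group = data.frame(
    group = c("A", "B", "C", "D"), n = 5L,
    mse = 0.1, cc = c(0.97, 0.95, 0.99, NA),
    cc_defined = c(TRUE, TRUE, TRUE, FALSE))),
    class = "evaluation_report")
  expect_setequal(select_probe_receptors(rep, 0.95), c("A", "C"))
  expect_length(select_probe_receptors(rep, 1.0), 0L)
})

# a stub model whose predictions depend only on the non-protein blocks:
# if probes leave descriptors, fingerprints and the mode flag untouched,
# every probed prediction must equal the baseline
test_that("probes never alter descriptor, fingerprint or mode columns", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 2L)
  fm <- assemble_synth(ds)
  nonprot <- c(block_columns(fm, "descriptor"),
               block_columns(fm, "fingerprint"),
               block_columns(fm, "mode_flag"))
  registerS3method("predict", "nonprotein_reader",
                   function(object, newdata, ...) {
                     if (inherits(newdata, "feature_matrix"))
                       newdata <- newdata$x
                     rowSums(newdata[, object$cols, drop = FALSE])
                   }, envir = asNamespace("gpcrmtl"))
  stub <- structure(list(
    ensemble = structure(list(cols = nonprot),
                         class = "nonprotein_reader"),
    mode_filter = "merged", blocks = fm$blocks,
    provenance = fm$provenance), class = "mtl_model")
  segs <- segment_protein_columns(fm$blocks[["protein"]], 7L)
  receptors <- unique(split$validation$receptor_id)

  tru <- truncation_test(stub, fm, split, segs, receptors)
  expect_equal(tru$probed_mse, tru$baseline_mse)
  per <- permutation_test(stub, fm, split, segs, receptors, seed = 5L)
  expect_equal(per$probed_mse, per$baseline_mse)
})

test_that("probe baselines equal the unprobed evaluation bit-for-bit", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 2L)
  fm <- assemble_synth(ds)
  mtl <- train_multitask(fm, split, "merged", specs = fast_specs(),
                         folds = 3L, seed = 2L)
  ev <- evaluate_model(mtl, fm, split, "validation")
  receptors <- unique(split$validation$receptor_id)
  segs <- segment_protein_columns(fm$blocks[["protein"]], 7L)
  tru <- truncation_test(mtl, fm, split, segs, receptors)
  for (r in receptors) {
    expect_identical(unique(tru$baseline_mse[tru$receptor_id == r]),
                     ev$per_group$mse[ev$per_group$group == r])
  }
  expect_true(all(tru$fold_change >= 0))
})

test_that("permutation probes are seed-deterministic", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 2L)
  fm <- assemble_synth(ds)
  mtl <- train_multitask(fm, split, "merged", specs = fast_specs(),
                         folds = 3L, seed = 2L)
  receptors <- unique(split$validation$receptor_id)
  segs <- segment_protein_columns(fm$blocks[["protein"]], 7L)
  p1 <- permutation_test(mtl, fm, split, segs, receptors, seed = 11L)
  p2 <- permutation_test(mtl, fm, split, segs, receptors, seed = 11L)
  expect_identical(p1, p2)
  p3 <- permutation_test(mtl, fm, split, segs, receptors, seed = 12L)
  expect_false(identical(p1$probed_mse, p3$probed_mse))
})

test_that("a feature-selected segment with no retained columns is flagged", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 3L)
  fm <- assemble_synth(ds)
  ranking <- mrmr_rank(fm, m = 8L)
  # keep only the top-ranked protein columns; most segments lose all
  # their protein columns
  red <- apply_selection(fm, ranking, m = 8L)
  mtl <- train_multitask(red, split, "merged", specs = fast_specs(),
                         folds = 3L, seed = 3L)
  L_full <- ds$config$L
  segs <- segment_protein_columns(L_full, 7L)
  receptors <- unique(split$validation$receptor_id)
  tru <- truncation_test(mtl, red, split, segs, receptors)
  empty_segments <- tru$segment[tru$empty_segment]
  expect_gt(length(unique(empty_segments)), 0L)
  expect_true(all(tru$fold_change[tru$empty_segment] == 1))
})

test_that("probe summaries aggregate per segment", {
  rep <- structure(data.frame(
    probe_kind = "truncation", segment = rep(1:2, each = 2),
    receptor_id = c("A", "B", "A", "B"), n = 3L,
    baseline_mse = 0.1, probed_mse = c(0.2, 0.4, 0.1, 0.1),
    fold_change = c(2, 4, 1, 1), empty_segment = FALSE,
    seed = NA_integer_), class = c("probe_report", "data.frame"))
  s <- summarize_probe(rep)
  expect_equal(s$mean_fold_change, c(3, 1))
  expect_equal(s$n_receptors, c(2L, 2L))
})
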