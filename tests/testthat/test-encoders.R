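test_that("residue property codes match the five published classes", {
  expect_equal(encode_residue("-"), 0L)
  expect_equal(encode_residue(c("C", "G", "P", "A")), rep(1L, 4))
  expect_equal(encode_residue(c("V", "I", "L", "M", "F", "Y", "W")),
               rep(2L, 7))
  expect_equal(encode_residue(c("S", "T", "N", "Q")), rep(3L, 4))
  expect_equal(encode_residue(c("D", "E", "R", "H", "K")), rep(4L, 5))
  # every amino acid covered, partition into the four non-gap classes
  all20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_setequal(unique(encode_residue(all20)), 1:4)
})

test_that("ambiguous residues error by default, can map to zero", {
  expect_error(encode_residue("X"), "X")
  expect_error(encode_residue("AXB"), "position")
  expect_warning(z <- encode_residue("AXA", ambiguous = "zero"), "ambiguous")
  expect_equal(z, c(1L, 0L, 1L))
})

test_that("alignment encoding applies the residue map element-wise", {
  expect_error(as_alignment(c(r1 = "ACD-", r2 = "ACD")), "same length")

  aln <- as_alignment(c(r1 = "ACD-", r2 = "ACD-"))
  codes <- encode_alignment(aln)
  expect_equal(unname(codes["r1", ]), c(1L, 1L, 4L, 0L))
  expect_identical(codes["r1", ], codes["r2", ])

  gap <- encode_alignment(as_alignment(c(g = "-----")))
  expect_equal(unname(gap[1, ]), rep(0L, 5))
})

test_that("alignment encoding names the offending receptor on error", {
  aln <- as_alignment(c(ok = "ACDE", bad = "ACDE"))
  aln$sequences[["bad"]] <- "ACXE"  # bypass construction check
  expect_error(encode_alignment(aln), "bad")
})

test_that("aligned FASTA round-trips through the reader", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">recA some description", "ACDEF-KLMN",
               ">recB", "ACDEF-KLMP"), fa)
  aln <- read_alignment(fa)
  expect_equal(aln$width, 10L)
  expect_setequal(names(aln$sequences), c("recA", "recB"))
  expect_equal(unname(aln$sequences[["recA"]]), "ACDEF-KLMN")
})

test_that("fingerprints are canonical, deterministic and 0/1", {
  fp1 <- compute_fingerprint("c1ccccc1", n_bits = 256L)
  fp2 <- compute_fingerprint("C1=CC=CC=C1", n_bits = 256L)  # kekulized benzene
  expect_identical(fp1, fp2)
  expect_true(all(fp1 %in% c(0L, 1L)))
  expect_gte(sum(fp1), 1L)
  expect_equal(length(fp1), 256L)
  expect_identical(compute_fingerprint("CCO"), compute_fingerprint("CCO"))
  expect_error(compute_fingerprint(""), "non-empty")
  expect_error(compute_fingerprint("not_a_smiles(("))
})

test_that("all fixture molecules featurize with at least one set bit", {
  got <- compute_fingerprints(
    data.frame(ligand_id = names(fixture_smiles),
               smiles = unname(fixture_smiles)), n_bits = 512L)
  expect_length(got$failed, 0L)
  expect_equal(nrow(got$fingerprints), length(fixture_smiles))
  expect_true(all(rowSums(got$fingerprints) >= 1))
})

test_that("descriptors are reproducible and size-monotone where expected", {
  recs <- data.frame(ligand_id = c("ethane", "hexane"),
                     smiles = c("CC", "CCCCCC"))
  d1 <- compute_descriptors(recs)$descriptors
  d2 <- compute_descriptors(recs)$descriptors
  expect_identical(d1, d2)
  expect_gt(d1["hexane", "MW"], d1["ethane", "MW"])
})

test_that("precomputed descriptor provider is a pure lookup", {
  recs <- data.frame(ligand_id = c("a", "b", "c"), smiles = NA)
  tab <- data.frame(ligand_id = c("a", "b"), d1 = c(1, 2), d2 = c(3, 4))
  got <- compute_descriptors(recs, provider = "precomputed", table = tab)
  expect_equal(got$descriptors["b", "d2"], 4)
  expect_equal(got$failed, "c")
})

test_that("assembled matrix has the block layout and width L + D + F + 1", {
  rec <- make_records(list(R1 = list(agonist = 2L, antagonist = 1L),
                           R2 = list(agonist = 1L)))
  codes <- rbind(R1 = c(1L, 2L, 0L), R2 = c(4L, 3L, 1L))
  colnames(codes) <- paste0("pos", 1:3)
  n_lig <- nrow(rec)
  fp <- matrix(rep(c(0L, 1L), length.out = n_lig * 8L), n_lig, 8L,
               dimnames = list(rec$ligand_id, NULL))
  desc <- matrix(seq_len(n_lig * 5L) / 10, n_lig, 5L,
                 dimnames = list(rec$ligand_id, NULL))
  fm <- assemble_features(rec, codes, fp, desc)

  expect_equal(ncol(fm$x), 3L + 5L + 8L + 1L)
  expect_equal(unname(fm$blocks), c(3L, 5L, 8L, 1L))
  expect_equal(fm$provenance$block[ncol(fm$x)], "mode_flag")
  # provenance partitions every column exactly once
  expect_equal(fm$provenance$column, seq_len(ncol(fm$x)))
  expect_equal(sum(fm$blocks), ncol(fm$x))
  # mode flag: agonist 1, antagonist 0
  expect_equal(unname(fm$x[, "mode_flag"]),
               as.numeric(rec$mode == "agonist"))
  # protein columns carry this receptor's codes
  expect_equal(unname(fm$x[rec$receptor_id == "R2", "prot1"]),
               rep(4, sum(rec$receptor_id == "R2")))
  # row order matches record order and labels travel along
  expect_equal(rownames(fm$x), rec$record_id)
  expect_equal(fm$labels, rec$label)
})

test_that("the reference block sizes give the 5023-wide design", {
  # L = 2554, D = 1444, F = 1024 plus the mode flag
  expect_equal(2554L + 1444L + 1024L + 1L, 5023L)
  rec <- make_records(list(R = list(agonist = 1L)))
  codes <- matrix(1L, 1, 2554, dimnames = list("R", NULL))
  fp <- matrix(0L, 1, 1024, dimnames = list(rec$ligand_id, NULL))
  fp[1, 1] <- 1L
  desc <- matrix(0, 1, 1444, dimnames = list(rec$ligand_id, NULL))
  fm <- assemble_features(rec, codes, fp, desc)
  expect_equal(ncol(fm$x), 5023L)
})

test_that("assembly fails loudly when a receptor or ligand is missing", {
  rec <- make_records(list(R1 = list(agonist = 1L)))
  codes <- matrix(1L, 1, 3, dimnames = list("OTHER", NULL))
  fp <- matrix(0L, 1, 4, dimnames = list(rec$ligand_id, NULL))
  expect_error(assemble_features(rec, codes, fp), "R1")
})

test_that("non-finite descriptors are imputed with frozen medians", {
  rec <- make_records(list(R = list(agonist = 5L)))
  codes <- matrix(1L, 1, 2, dimnames = list("R", NULL))
  fp <- matrix(1L, 5, 4, dimnames = list(rec$ligand_id, NULL))
  desc <- matrix(c(1, 2, NA, 4, 100), 5, 1,
                 dimnames = list(rec$ligand_id, NULL))
  fm <- assemble_features(rec, codes, fp, desc)
  expect_equal(unname(fm$x[3, 3]), 3)          # median of 1,2,4,100
  # frozen imputation value reused on new data
  fm2 <- assemble_features(rec, codes, fp, desc, impute = fm$impute)
  expect_equal(unname(fm2$x[3, 3]), 3)
})

test_that("encoding is pure: identical inputs yield identical matrices", {
  ds <- small_synth(seed = 3L)
  fm1 <- assemble_synth(ds)
  fm2 <- assemble_synth(ds)
  expect_identical(fm1$x, fm2$x)
  # protein columns only hold codes 0..4; fingerprint columns only 0/1
  expect_true(all(fm1$x[, block_columns(fm1, "protein")] %in% 0:4))
  expect_true(all(fm1$x[, block_columns(fm1, "fingerprint")] %in% 0:1))
})
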