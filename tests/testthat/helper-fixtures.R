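# Shared fixtures built in code at test time.

# ten hand-written valid SMILES used for chemistry-toolkit featurization
fixture_smiles <- c(
  benzene      = "c1ccccc1",
  ethanol      = "CCO",
  acetic_acid  = "CC(=O)O",
  toluene      = "Cc1ccccc1",
  phenol       = "Oc1ccccc1",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
  serotonin    = "NCCc1c[nH]c2ccc(O)cc12",
  histamine    = "NCCc1c[nH]cn1",
  tryptamine   = "NCCc1c[nH]c2ccccc12"
)

# small bioactivity table written to a temp file
write_toy_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("receptor_id\tligand_id\tsmiles\tmode\tec50_nM", rows), path)
  path
}

# deterministic toy record set: n records for each (receptor, mode) pair
make_records <- function(counts) {
  rows <- list()
  i <- 0L
  for (r in names(counts)) {
    for (m in names(counts[[r]])) {
      k <- counts[[r]][[m]]
      if (k == 0) next
      idx <- i + seq_len(k)
      rows[[paste(r, m)]] <- data.frame(
        record_id = sprintf("rec%05d", idx),
        receptor_id = r, ligand_id = sprintf("lig%05d", idx),
        smiles = NA_character_, mode = m,
        ec50_nM = 10^seq(0, 3, length.out = k),
        label = seq(0, 3, length.out = k),
        stringsAsFactors = FALSE)
      i <- i + k
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small synthetic dataset for model-level tests (fast)
small_synth <- function(seed = 1L) {
  cfg <- synth_config(n_families = 2L, receptors_per_family = 3L,
                      L = 70L, records_per_receptor = 40L,
                      n_lowdata = 2L, n_orphan = 1L,
                      n_fingerprint_bits = 32L, n_informative = 8L,
                      seed = seed)
  generate_records(cfg)
}

fast_specs <- function() default_learners(c("gbdt_a", "random_forest"),
                                          fast = TRUE)
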