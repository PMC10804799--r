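#' Configuration for the synthetic GPCR benchmark generator
#'
#' Defines a family of aligned synthetic receptors and per-receptor
#' ligand activity records with fully known ground truth: the
#' log10-EC50 label is a planted function of protein property codes at
#' informative alignment positions (concentrated in one segment),
#' ligand fingerprint bits, position-by-bit interactions and the
#' agonist/antagonist mode, plus Gaussian noise. The records-per-receptor
#' distribution is skewed, with a few low-data receptors and a few
#' orphan-like receptors below the orphan threshold.
#'
#' @param n_families number of receptor families (distinct ancestral
#'   sequences).
#' @param receptors_per_family regular receptors per family.
#' @param L alignment width; default 210, divisible by the 7 probe
#'   segments.
#' @param k segment count the informative block is defined against.
#' @param gap_fraction fraction of alignment positions gapped in each
#'   family's ancestor.
#' @param mutation_rate per-position probability that a family member's
#'   non-gap code differs from the ancestor at non-informative positions
#'   (keeps families recognizable).
#' @param informative_match_rate fraction of receptors carrying the
#'   preferred code at each informative position. The assignment is
#'   balanced within each family (and within its regular and
#'   low-data/orphan strata), so family membership stays orthogonal to
#'   the planted potency signal and proxies of family identity elsewhere
#'   in the alignment carry none of it.
#' @param n_informative number of informative alignment positions
#'   (default 20), all placed inside \code{informative_segment}.
#' @param informative_segment which of the k segments carries the
#'   informative positions (default 1, the N-terminal part).
#' @param effect_range range of the per-position effect weights a_j.
#' @param n_fingerprint_bits synthetic fingerprint length F (default 64).
#' @param fp_density Bernoulli density of fingerprint bits.
#' @param n_active_bits number of label-active fingerprint bits.
#' @param active_range range of the active-bit weights g_b.
#' @param n_interactions number of sparse (position x bit) interaction
#'   terms.
#' @param interaction_range range of the interaction weights.
#' @param mode_offset label offset added to agonist records.
#' @param noise_sd standard deviation of the Gaussian label noise
#'   (log10 units).
#' @param records_per_receptor records for each regular receptor.
#' @param n_lowdata,lowdata_records extra low-data receptors (share the
#'   families) and their record counts; these stay above the orphan
#'   threshold but give single-task models little to learn from.
#' @param n_orphan,orphan_records extra orphan-like receptors with fewer
#'   records than the orphan threshold of 8.
#' @param n_informative_descriptors descriptor columns that are noisy
#'   copies of the weighted active-bit sum (recoverable by feature
#'   selection).
#' @param n_noise_descriptors pure-noise descriptor columns.
#' @param seed master seed; all stages derive named child seeds from it.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_families = 4L, receptors_per_family = 6L,
                         L = 210L, k = 7L,
                         gap_fraction = 0.1, mutation_rate = 0.05,
                         informative_match_rate = 0.5,
                         n_informative = 20L, informative_segment = 1L,
                         effect_range = c(0.9, 1.1),
                         n_fingerprint_bits = 64L, fp_density = 0.2,
                         n_active_bits = 10L, active_range = c(0.4, 0.8),
                         n_interactions = 10L,
                         interaction_range = c(0.2, 0.5),
                         mode_offset = 0.5, noise_sd = 0.2,
                         records_per_receptor = 80L,
                         n_lowdata = 6L, lowdata_records = 12L,
                         n_orphan = 3L, orphan_records = 5L,
                         n_informative_descriptors = 3L,
                         n_noise_descriptors = 5L,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_sd > 0, cfg$L >= cfg$k,
            cfg$informative_segment >= 1L, cfg$informative_segment <= cfg$k)
  seg <- segment_protein_columns(cfg$L, cfg$k)
  seg_size <- seg$size[cfg$informative_segment]
  if (cfg$n_informative > seg_size)
    stop("n_informative exceeds the informative segment's width (",
         seg_size, ")")
  structure(cfg, class = "synth_config")
}

.code_to_residue <- c("-", "A", "L", "S", "K")  # codes 0..4

#' Generate a synthetic receptor family alignment
#'
#' Draws one ancestral property-code vector per family (uniform codes
#' 1..4 with a gapped fraction), derives members by per-position
#' mutation, overwrites the informative positions with a balanced
#' stratified assignment of preferred/other codes (see
#' [synth_config()]), and emits aligned
#' residue strings using one representative residue per property class
#' (1 to A, 2 to L, 3 to S, 4 to K, 0 to '-') so that
#' [encode_alignment()] reproduces the internal code matrix exactly.
#'
#' @param config a \code{synth_config}.
#' @return list with \code{alignment} (an \code{alignment_matrix}),
#'   \code{codes} (the internal code matrix), \code{family} (named
#'   vector receptor id to family), \code{n_records} (named vector of
#'   planned records per receptor) and \code{informative} (data frame
#'   position, preferred_code, weight).
#' @export
generate_receptor_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  seg <- segment_protein_columns(cfg$L, cfg$k)

  set.seed(child_seed(cfg$seed, "informative"))
  seg_cols <- seq(seg$start[cfg$informative_segment],
                  seg$end[cfg$informative_segment])
  pos <- sort(sample(seg_cols, cfg$n_informative))
  informative <- data.frame(
    position = pos,
    preferred_code = sample(1:4, cfg$n_informative, replace = TRUE),
    weight = stats::runif(cfg$n_informative, cfg$effect_range[1],
                          cfg$effect_range[2]))

  set.seed(child_seed(cfg$seed, "alignment"))
  ## receptor roster: regular members, then low-data, then orphan-like,
  ## the extras cycled over the families so every family is shared
  fam_of <- c(rep(seq_len(cfg$n_families), each = cfg$receptors_per_family),
              rep_len(seq_len(cfg$n_families), cfg$n_lowdata),
              rep_len(seq_len(cfg$n_families), cfg$n_orphan))
  ids <- c(sprintf("fam%d_r%d", rep(seq_len(cfg$n_families),
                                    each = cfg$receptors_per_family),
                   rep(seq_len(cfg$receptors_per_family), cfg$n_families)),
           sprintf("lowdata_%d", seq_len(cfg$n_lowdata)),
           sprintf("orphan_%d", seq_len(cfg$n_orphan)))
  n_records <- stats::setNames(
    c(rep(cfg$records_per_receptor,
          cfg$n_families * cfg$receptors_per_family),
      rep(cfg$lowdata_records, cfg$n_lowdata),
      rep(cfg$orphan_records, cfg$n_orphan)), ids)

  ancestors <- lapply(seq_len(cfg$n_families), function(f) {
    codes <- sample(1:4, cfg$L, replace = TRUE)
    gaps <- sample(setdiff(seq_len(cfg$L), informative$position),
                   round(cfg$gap_fraction * cfg$L))
    codes[gaps] <- 0L
    codes
  })
  codes <- t(vapply(seq_along(ids), function(i) {
    anc <- ancestors[[fam_of[i]]]
    mut <- anc != 0L & stats::runif(cfg$L) < cfg$mutation_rate
    anc[mut] <- sample(1:4, sum(mut), replace = TRUE)
    anc
  }, integer(cfg$L)))

  ## informative codes are assigned by stratified balanced draw: within
  ## each family, and separately among its regular and extra
  ## (low-data/orphan) members, match_rate of the receptors carry the
  ## preferred code and the rest a random other code. Family membership
  ## is thereby orthogonal to the planted signal, so family-identity
  ## proxies elsewhere in the alignment carry no potency information.
  n_regular <- cfg$n_families * cfg$receptors_per_family
  strata <- split(seq_along(ids),
                  interaction(fam_of, seq_along(ids) <= n_regular,
                              drop = TRUE))
  for (t in seq_len(nrow(informative))) {
    pref <- informative$preferred_code[t]
    newcol <- integer(length(ids))
    for (members in strata) {
      m <- length(members)
      target <- cfg$informative_match_rate * m
      k <- floor(target) + stats::rbinom(1L, 1L, target - floor(target))
      hit <- if (k > 0L) sample(members, k) else integer(0)
      newcol[hit] <- pref
      rest <- setdiff(members, hit)
      newcol[rest] <- sample(setdiff(1:4, pref), length(rest),
                             replace = TRUE)
    }
    codes[, informative$position[t]] <- newcol
  }
  rownames(codes) <- ids
  colnames(codes) <- paste0("pos", seq_len(cfg$L))

  seqs <- apply(codes, 1, function(v)
    paste(.code_to_residue[v + 1L], collapse = ""))
  list(alignment = as_alignment(seqs), codes = codes,
       family = stats::setNames(fam_of, ids),
       n_records = n_records, informative = informative)
}

#' Generate synthetic bioactivity records with ground truth
#'
#' Per record: a fresh synthetic ligand is drawn as independent Bernoulli
#' fingerprint bits plus a descriptor block (standard normal noise
#' columns and a few informative columns proportional to the weighted
#' active-bit sum), the mode is a fair coin, and the noiseless label is
#' the planted linear-plus-interaction function of the receptor's codes,
#' the ligand bits and the mode. The emitted label adds
#' Normal(0, noise_sd) and EC50 is 10^label nM, so the data-loading
#' log-transform round-trips.
#'
#' @param config a \code{synth_config}.
#' @param family output of [generate_receptor_family()] for the same
#'   config.
#' @return an object of class \code{synth_dataset}: list with
#'   \code{records} (bioactivity data frame), \code{alignment},
#'   \code{codes}, \code{fingerprints}, \code{descriptors} (per-ligand
#'   matrices) and \code{truth} (noiseless labels, noise draws, family
#'   map, informative positions/weights, active bits, interactions).
#' @export
generate_records <- function(config, family = generate_receptor_family(config)) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  codes <- family$codes
  inf <- family$informative

  set.seed(child_seed(cfg$seed, "activebits"))
  active_bits <- sort(sample(seq_len(cfg$n_fingerprint_bits),
                             cfg$n_active_bits))
  active_w <- stats::runif(cfg$n_active_bits, cfg$active_range[1],
                           cfg$active_range[2])
  interactions <- data.frame(
    position = sample(inf$position, cfg$n_interactions, replace = TRUE),
    bit = sample(active_bits, cfg$n_interactions, replace = TRUE),
    gamma = stats::runif(cfg$n_interactions, cfg$interaction_range[1],
                         cfg$interaction_range[2]))

  n_total <- sum(family$n_records)
  receptor_id <- rep(names(family$n_records), family$n_records)

  set.seed(child_seed(cfg$seed, "ligands"))
  F <- cfg$n_fingerprint_bits
  fp <- matrix(as.integer(stats::runif(n_total * F) < cfg$fp_density),
               nrow = n_total, ncol = F)
  colnames(fp) <- paste0("fp", seq_len(F))
  active_sum <- as.numeric(fp[, active_bits, drop = FALSE] %*% active_w)
  D <- cfg$n_informative_descriptors + cfg$n_noise_descriptors
  desc <- matrix(stats::rnorm(n_total * D), nrow = n_total, ncol = D)
  for (j in seq_len(cfg$n_informative_descriptors))
    desc[, j] <- active_sum * (0.5 + 0.5 * j) + 0.1 * desc[, j]
  colnames(desc) <- c(paste0("idesc", seq_len(cfg$n_informative_descriptors)),
                      paste0("ndesc", seq_len(cfg$n_noise_descriptors)))

  set.seed(child_seed(cfg$seed, "mode"))
  mode <- sample(c("agonist", "antagonist"), n_total, replace = TRUE)

  match_mat <- codes[receptor_id, inf$position, drop = FALSE] ==
    matrix(inf$preferred_code, nrow = n_total, ncol = nrow(inf),
           byrow = TRUE)
  protein_term <- as.numeric(match_mat %*% inf$weight)
  inter_term <- numeric(n_total)
  for (t in seq_len(nrow(interactions))) {
    jm <- codes[receptor_id, interactions$position[t]] ==
      inf$preferred_code[match(interactions$position[t], inf$position)]
    inter_term <- inter_term +
      interactions$gamma[t] * jm * fp[, interactions$bit[t]]
  }
  noiseless <- as.numeric(protein_term + active_sum + inter_term +
                            cfg$mode_offset * (mode == "agonist"))

  set.seed(child_seed(cfg$seed, "noise"))
  noise <- stats::rnorm(n_total, 0, cfg$noise_sd)
  label <- noiseless + noise

  ligand_id <- sprintf("lig%05d", seq_len(n_total))
  rownames(fp) <- ligand_id
  rownames(desc) <- ligand_id
  records <- data.frame(
    record_id = sprintf("rec%05d", seq_len(n_total)),
    receptor_id = receptor_id,
    ligand_id = ligand_id,
    smiles = NA_character_,
    mode = mode,
    ec50_nM = 10^label,
    label = label,
    stringsAsFactors = FALSE)

  truth <- list(noiseless = noiseless, noise = noise,
                family = family$family, informative = inf,
                active_bits = data.frame(bit = active_bits,
                                         weight = active_w),
                interactions = interactions,
                informative_segment = cfg$informative_segment)
  structure(list(records = records, alignment = family$alignment,
                 codes = codes, fingerprints = fp, descriptors = desc,
                 truth = truth, config = cfg),
            class = "synth_dataset")
}

#' Generate a complete synthetic dataset
#'
#' @param config a \code{synth_config} (default: package defaults).
#' @param seed optional master-seed override.
#' @return a \code{synth_dataset}; see [generate_records()].
#' @export
generate_synthetic_dataset <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  generate_records(config)
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic GPCR bioactivity dataset:", nrow(x$records), "records,",
      nrow(x$codes), "receptors, alignment width", ncol(x$codes), "\n")
  cat("  informative positions:",
      paste(x$truth$informative$position, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the feature matrix of a synthetic dataset
#'
#' @param ds a \code{synth_dataset}.
#' @return a \code{feature_matrix} built from the dataset's code matrix,
#'   fingerprints and descriptors.
#' @export
assemble_synth <- function(ds) {
  stopifnot(inherits(ds, "synth_dataset"))
  assemble_features(ds$records, ds$codes, ds$fingerprints, ds$descriptors)
}

#' Write synthetic fixtures to disk
#'
#' Emits the delimited bioactivity table, the aligned FASTA, per-ligand
#' fingerprint and descriptor tables, and a ground-truth sidecar; the
#' bioactivity table and alignment re-load byte-identically through
#' [load_bioactivity_table()] and [read_alignment()].
#'
#' @param ds a \code{synth_dataset}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_fixtures <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  paths <- c(
    bioactivity = file.path(dir, "bioactivity.tsv"),
    alignment = file.path(dir, "alignment.fasta"),
    fingerprints = file.path(dir, "ligand_fingerprints.tsv"),
    descriptors = file.path(dir, "ligand_descriptors.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))

  tab <- ds$records[, c("record_id", "receptor_id", "ligand_id", "smiles",
                        "mode", "ec50_nM")]
  tab$ec50_nM <- sprintf("%.17g", tab$ec50_nM)
  utils::write.table(tab, paths[["bioactivity"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  aa <- Biostrings::AAStringSet(ds$alignment$sequences)
  Biostrings::writeXStringSet(aa, paths[["alignment"]], width = 80L)

  fp <- data.frame(ligand_id = rownames(ds$fingerprints),
                   ds$fingerprints, check.names = FALSE)
  utils::write.table(fp, paths[["fingerprints"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de <- data.frame(ligand_id = rownames(ds$descriptors),
                   format(ds$descriptors, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(de, paths[["descriptors"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tr <- ds$truth$informative
  tr$kind <- "informative_position"
  utils::write.table(tr[, c("kind", "position", "preferred_code", "weight")],
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
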