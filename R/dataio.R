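#' Read a GPCR bioactivity table
#'
#' Reads a delimited table of receptor-ligand EC50 measurements, keeps only
#' rows with a recognizable interaction mode (agonist or antagonist) and a
#' positive numeric EC50 in nanomolar, and attaches the log10(EC50/nM)
#' modelling label. The separator is auto-detected from the file extension
#' (\code{.csv} vs \code{.tsv}/\code{.txt}).
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param columns named character vector mapping the canonical roles
#'   \code{receptor}, \code{ligand}, \code{smiles}, \code{mode}, \code{ec50}
#'   to column names in the file. \code{smiles} and \code{ligand} may be
#'   absent from the file only if the other is present (the present one is
#'   reused as identifier).
#' @param collapse_duplicates if \code{TRUE}, duplicate
#'   (receptor, ligand, mode) records are collapsed to their median EC50.
#'   Default keeps duplicates as independent measurements.
#' @return a data frame of bioactivity records with columns
#'   \code{record_id}, \code{receptor_id}, \code{ligand_id}, \code{smiles},
#'   \code{mode}, \code{ec50_nM} and \code{label} (= log10 EC50 in nM),
#'   with a \code{load_report} attribute listing kept/dropped counts and
#'   per-row rejection reasons.
#' @export
load_bioactivity_table <- function(path,
                                   columns = c(receptor = "receptor_id",
                                               ligand   = "ligand_id",
                                               smiles   = "smiles",
                                               mode     = "mode",
                                               ec50     = "ec50_nM"),
                                   collapse_duplicates = FALSE) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  required <- c("receptor", "mode", "ec50")
  for (role in required) {
    if (!columns[[role]] %in% names(raw))
      stop("required column '", columns[[role]], "' (role: ", role,
           ") missing from ", path)
  }
  has_lig <- !is.na(columns["ligand"]) && columns[["ligand"]] %in% names(raw)
  has_smi <- !is.na(columns["smiles"]) && columns[["smiles"]] %in% names(raw)
  if (!has_lig && !has_smi)
    stop("table must contain a ligand identifier column ('",
         columns[["ligand"]], "') or a SMILES column ('",
         columns[["smiles"]], "')")

  n <- nrow(raw)
  receptor <- trimws(as.character(raw[[columns[["receptor"]]]]))
  mode_raw <- as.character(raw[[columns[["mode"]]]])
  ec50_raw <- raw[[columns[["ec50"]]]]
  ligand <- if (has_lig) trimws(as.character(raw[[columns[["ligand"]]]])) else NULL
  smiles <- if (has_smi) trimws(as.character(raw[[columns[["smiles"]]]])) else NULL
  if (is.null(ligand)) ligand <- smiles
  if (is.null(smiles)) smiles <- NA_character_

  mode <- normalize_mode(mode_raw)
  ec50 <- suppressWarnings(as.numeric(as.character(ec50_raw)))

  reason <- rep(NA_character_, n)
  reason[is.na(mode)] <- "missing or unrecognized mode"
  bad_ec50 <- is.na(reason) & (is.na(ec50) | !is.finite(ec50) | ec50 <= 0)
  reason[bad_ec50] <- "missing, non-numeric or non-positive EC50"
  keep <- is.na(reason)

  records <- data.frame(
    record_id   = sprintf("rec%05d", seq_len(sum(keep))),
    receptor_id = receptor[keep],
    ligand_id   = ligand[keep],
    smiles      = if (length(smiles) == n) smiles[keep] else NA_character_,
    mode        = mode[keep],
    ec50_nM     = ec50[keep],
    label       = log10(ec50[keep]),
    stringsAsFactors = FALSE
  )

  if (collapse_duplicates && nrow(records) > 0L) {
    key <- paste(records$receptor_id, records$ligand_id, records$mode, sep = "\r")
    med <- tapply(records$ec50_nM, key, stats::median)
    first <- records[!duplicated(key), , drop = FALSE]
    first$ec50_nM <- as.numeric(med[paste(first$receptor_id, first$ligand_id,
                                          first$mode, sep = "\r")])
    first$label <- log10(first$ec50_nM)
    first$record_id <- sprintf("rec%05d", seq_len(nrow(first)))
    records <- first
  }

  attr(records, "load_report") <- list(
    n_input = n,
    n_kept = nrow(records),
    n_dropped = sum(!keep),
    rejections = data.frame(row = which(!keep),
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
  records
}

#' Normalize agonist/antagonist mode strings
#'
#' Case-insensitive with surrounding whitespace stripped; anything that is
#' not exactly \code{agonist} or \code{antagonist} after normalization
#' (including \code{NA} and the empty string) becomes \code{NA}.
#'
#' @param x character vector of raw mode strings.
#' @return character vector with values in \code{c("agonist", "antagonist", NA)}.
#' @export
normalize_mode <- function(x) {
  v <- tolower(trimws(as.character(x)))
  v[!v %in% c("agonist", "antagonist")] <- NA_character_
  v
}

#' Partition receptors into modelled and orphan sets
#'
#' Receptors whose total record count (summed over agonist and antagonist
#' modes) falls below \code{threshold} are held out as orphan receptors,
#' used only for independent testing; the rest are available for model
#' training and validation.
#'
#' @param records a bioactivity record data frame
#'   (see [load_bioactivity_table()]).
#' @param threshold minimum total record count for a receptor to be
#'   modelled (default 8: receptors with fewer than 8 bioactivities are
#'   orphans).
#' @return a list with elements \code{modelled} and \code{orphan} (record
#'   data frames) and \code{counts} (per-receptor record counts).
#' @export
split_orphan_receptors <- function(records, threshold = 8L) {
  stopifnot(threshold >= 1L)
  if (nrow(records) == 0L) {
    warning("no records to partition")
    return(list(modelled = records, orphan = records,
                counts = integer(0)))
  }
  counts <- table(records$receptor_id)
  orphan_ids <- names(counts)[counts < threshold]
  is_orphan <- records$receptor_id %in% orphan_ids
  list(modelled = records[!is_orphan, , drop = FALSE],
       orphan   = records[is_orphan, , drop = FALSE],
       counts   = as.integer(counts) |> stats::setNames(names(counts)))
}

#' Stratified train/validation split of bioactivity records
#'
#' Splits records independently within each (receptor, mode) group at the
#' given ratio, then merges the per-group training and validation sets.
#' Within a group of size n, ceiling(ratio * n) records go to training when
#' n < 5 (so a singleton group trains), otherwise round(ratio * n); the
#' assignment is a seeded random draw and is reproducible.
#'
#' @param records orphan-filtered bioactivity records.
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed controlling the random assignment.
#' @param orphan_test optional record data frame of orphan receptors,
#'   carried through unchanged as the held-out test partition.
#' @return an object of class \code{dataset_split}: a list with record data
#'   frames \code{train}, \code{validation}, \code{orphan_test}, plus the
#'   \code{ratio}, \code{seed} and a \code{manifest} data frame
#'   (record_id, receptor_id, mode, partition).
#' @export
stratified_split <- function(records, ratio = 0.8, seed = 1L,
                             orphan_test = NULL) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("ratio must be a single number strictly between 0 and 1")
  grp <- interaction(records$receptor_id, records$mode, drop = TRUE)
  part <- rep("train", nrow(records))
  rng <- local({
    set.seed(as.integer(seed) %% 2147483647L)
    lapply(split(seq_len(nrow(records)), grp), function(idx) {
      n <- length(idx)
      n_train <- if (n < 5L) ceiling(ratio * n) else round(ratio * n)
      n_train <- max(1L, min(n, n_train))
      idx[sample.int(n) > n_train]   # indices sent to validation
    })
  })
  part[unlist(rng, use.names = FALSE)] <- "validation"

  train <- records[part == "train", , drop = FALSE]
  validation <- records[part == "validation", , drop = FALSE]
  if (is.null(orphan_test))
    orphan_test <- records[0, , drop = FALSE]

  manifest_part <- function(d, name)
    data.frame(record_id = d$record_id, receptor_id = d$receptor_id,
               mode = d$mode, partition = rep(name, nrow(d)),
               stringsAsFactors = FALSE)
  manifest <- rbind(manifest_part(train, "train"),
                    manifest_part(validation, "validation"),
                    manifest_part(orphan_test, "orphan_test"))
  structure(list(train = train, validation = validation,
                 orphan_test = orphan_test, ratio = ratio,
                 seed = as.integer(seed), orphan_threshold = NA_integer_,
                 manifest = manifest),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Bioactivity dataset split (ratio ", x$ratio, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  train:      ", nrow(x$train), " records, ",
      length(unique(x$train$receptor_id)), " receptors\n", sep = "")
  cat("  validation: ", nrow(x$validation), " records\n", sep = "")
  cat("  orphan test:", nrow(x$orphan_test), "records,",
      length(unique(x$orphan_test$receptor_id)), "receptors\n")
  invisible(x)
}

#' Write a split manifest to a TSV file
#'
#' @param split a \code{dataset_split}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  utils::write.table(split$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Prepare modelling data from a bioactivity table
#'
#' Convenience wrapper chaining [load_bioactivity_table()],
#' [split_orphan_receptors()] and [stratified_split()].
#'
#' @inheritParams load_bioactivity_table
#' @inheritParams stratified_split
#' @param orphan_threshold per-receptor record count below which a receptor
#'   is held out as orphan (default 8).
#' @return a \code{dataset_split} whose \code{orphan_test} partition holds
#'   all records of orphan receptors.
#' @export
prepare_dataset <- function(path, ratio = 0.8, seed = 1L,
                            orphan_threshold = 8L,
                            columns = c(receptor = "receptor_id",
                                        ligand   = "ligand_id",
                                        smiles   = "smiles",
                                        mode     = "mode",
                                        ec50     = "ec50_nM"),
                            collapse_duplicates = FALSE) {
  records <- load_bioactivity_table(path, columns = columns,
                                    collapse_duplicates = collapse_duplicates)
  parts <- split_orphan_receptors(records, threshold = orphan_threshold)
  split <- stratified_split(parts$modelled, ratio = ratio, seed = seed,
                            orphan_test = parts$orphan)
  split$orphan_threshold <- as.integer(orphan_threshold)
  attr(split, "load_report") <- attr(records, "load_report")
  split
}
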