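## Amino-acid property classes used to encode alignment columns:
##   0 gap/padding; 1 special side chains (C G P A); 2 hydrophobic
##   (V I L M F Y W); 3 polar uncharged (S T N Q); 4 charged (D E R H K)
.residue_code_map <- c(
  "-" = 0L,
  C = 1L, G = 1L, P = 1L, A = 1L,
  V = 2L, I = 2L, L = 2L, M = 2L, F = 2L, Y = 2L, W = 2L,
  S = 3L, T = 3L, N = 3L, Q = 3L,
  D = 4L, E = 4L, R = 4L, H = 4L, K = 4L
)

#' Encode amino acids as side-chain property classes
#'
#' Maps each residue of an aligned sequence to an integer property class:
#' 0 for the alignment gap character \code{-}, 1 for special side chains
#' (C, G, P, A), 2 for hydrophobic (V, I, L, M, F, Y, W), 3 for polar
#' uncharged (S, T, N, Q) and 4 for electrically charged (D, E, R, H, K).
#'
#' @param residues character vector of single residue letters (or a single
#'   multi-character string, which is split).
#' @param ambiguous what to do with letters outside the 20 canonical amino
#'   acids plus gap (e.g. B, J, O, U, X, Z): \code{"error"} (default) or
#'   \code{"zero"} to code them as 0 with a warning.
#' @return integer vector of codes in 0..4.
#' @export
encode_residue <- function(residues, ambiguous = c("error", "zero")) {
  ambiguous <- match.arg(ambiguous)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  codes <- .residue_code_map[toupper(residues)]
  bad <- which(is.na(codes))
  if (length(bad)) {
    if (ambiguous == "error")
      stop("unrecognized residue(s) ", paste0("'", residues[bad], "'",
           collapse = ", "), " at position(s) ",
           paste(bad, collapse = ", "))
    warning(length(bad), " ambiguous residue(s) coded as 0")
    codes[bad] <- 0L
  }
  unname(codes)
}

#' Read an aligned FASTA file of receptor sequences
#'
#' @param path aligned FASTA; gaps must be dashes and all sequences the
#'   same length.
#' @return an object of class \code{alignment_matrix}: a list with
#'   \code{sequences} (named character vector) and \code{width}.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  as_alignment(seqs)
}

#' Construct an alignment matrix from named sequences
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths, residues among the 20 amino-acid letters plus \code{-}).
#' @return an \code{alignment_matrix}.
#' @export
as_alignment <- function(sequences) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  w <- unique(nchar(sequences))
  if (length(w) != 1L)
    stop("aligned sequences must all have the same length; found widths ",
         paste(w, collapse = ", "))
  allowed <- c(names(.residue_code_map))
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(toupper(chars), allowed)
  if (length(bad))
    stop("alignment contains disallowed characters: ",
         paste(bad, collapse = ", "))
  structure(list(sequences = sequences, width = w),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat("Alignment of", length(x$sequences), "receptor sequences, width",
      x$width, "\n")
  invisible(x)
}

#' Encode an alignment as property-code vectors
#'
#' Applies [encode_residue()] position-wise to every sequence.
#'
#' @param alignment an \code{alignment_matrix} from [read_alignment()] or
#'   [as_alignment()].
#' @param ambiguous passed to [encode_residue()].
#' @return integer matrix (receptors x alignment width) of codes 0..4 with
#'   receptor ids as row names.
#' @export
encode_alignment <- function(alignment, ambiguous = c("error", "zero")) {
  stopifnot(inherits(alignment, "alignment_matrix"))
  ambiguous <- match.arg(ambiguous)
  codes <- t(vapply(names(alignment$sequences), function(id) {
    tryCatch(encode_residue(alignment$sequences[[id]], ambiguous),
             error = function(e)
               stop("receptor '", id, "': ", conditionMessage(e),
                    call. = FALSE))
  }, integer(alignment$width)))
  rownames(codes) <- names(alignment$sequences)
  colnames(codes) <- paste0("pos", seq_len(alignment$width))
  codes
}

#' Extended-connectivity fingerprint of a molecule
#'
#' Computes a circular (extended-connectivity) fingerprint with the given
#' maximum atom-environment diameter via OpenBabel, and folds it to
#' \code{n_bits} by OR-ing bit indices modulo \code{n_bits}.
#'
#' @param smiles a single SMILES string.
#' @param n_bits folded fingerprint length (default 1024).
#' @param diameter maximum environment diameter in bonds; must be one of
#'   0, 2, 4, 6, 8, 10 (default 6, i.e. radius 3).
#' @return integer 0/1 vector of length \code{n_bits}.
#' @export
compute_fingerprint <- function(smiles, n_bits = 1024L, diameter = 6L) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("smiles must be a single non-empty string")
  if (!diameter %in% c(0L, 2L, 4L, 6L, 8L, 10L))
    stop("diameter must be one of 0, 2, 4, 6, 8, 10")
  raw <- .ob_fingerprint(smiles, paste0("ECFP", diameter))
  if (is.null(raw) || sum(raw) == 0L)
    stop("SMILES could not be parsed or yields an empty fingerprint: ",
         smiles)
  folded <- integer(n_bits)
  on_bits <- which(raw != 0) - 1L
  folded[(on_bits %% n_bits) + 1L] <- 1L
  folded
}

.ob_fingerprint <- function(smiles, name) {
  out <- tryCatch(suppressWarnings({
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    ChemmineOB::fingerprint_OB(mol, name)
  }), error = function(e) NULL)
  if (is.matrix(out)) out <- out[1, ]
  out
}

#' Fingerprints for a set of records
#'
#' Vectorized [compute_fingerprint()] over the unique SMILES of a record
#' table. Ligands whose SMILES cannot be parsed are reported, not silently
#' zero-filled.
#'
#' @param records bioactivity record data frame with \code{ligand_id} and
#'   \code{smiles} columns.
#' @inheritParams compute_fingerprint
#' @return list with \code{fingerprints} (0/1 matrix, one row per unique
#'   ligand, ligand ids as row names) and \code{failed} (character vector
#'   of ligand ids that could not be featurized).
#' @export
compute_fingerprints <- function(records, n_bits = 1024L, diameter = 6L) {
  uniq <- records[!duplicated(records$ligand_id),
                  c("ligand_id", "smiles"), drop = FALSE]
  rows <- lapply(seq_len(nrow(uniq)), function(i)
    tryCatch(compute_fingerprint(uniq$smiles[i], n_bits, diameter),
             error = function(e) NULL))
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok))
    stop("no ligand could be featurized; first SMILES was: ",
         uniq$smiles[1])
  fp <- do.call(rbind, rows[ok])
  rownames(fp) <- uniq$ligand_id[ok]
  colnames(fp) <- paste0("fp", seq_len(n_bits))
  list(fingerprints = fp, failed = uniq$ligand_id[!ok])
}

#' Physicochemical descriptors for a set of records
#'
#' Computes a fixed-length real-valued descriptor vector per unique ligand.
#' The \code{"openbabel"} provider uses the numeric 2-D properties exposed
#' by OpenBabel (hydrogen-bond acceptors/donors, logP, molar refractivity,
#' molecular weight, fluorine count, TPSA); the \code{"precomputed"}
#' provider looks vectors up by \code{ligand_id} in a user-supplied table,
#' e.g. a PaDEL export.
#'
#' @param records bioactivity record data frame.
#' @param provider \code{"openbabel"} or \code{"precomputed"}.
#' @param table for \code{provider = "precomputed"}: a data frame or matrix
#'   of descriptors with ligand ids as row names (or a \code{ligand_id}
#'   column).
#' @return list with \code{descriptors} (numeric matrix, ligand ids as row
#'   names), \code{provider}, and \code{failed} (ligand ids without
#'   descriptors).
#' @export
compute_descriptors <- function(records,
                                provider = c("openbabel", "precomputed"),
                                table = NULL) {
  provider <- match.arg(provider)
  uniq <- records[!duplicated(records$ligand_id), , drop = FALSE]
  if (provider == "precomputed") {
    if (is.null(table)) stop("provider 'precomputed' requires a table")
    if (is.data.frame(table) && "ligand_id" %in% names(table)) {
      rownames(table) <- table$ligand_id
      table <- table[, setdiff(names(table), "ligand_id"), drop = FALSE]
    }
    tab <- as.matrix(table)
    hit <- uniq$ligand_id %in% rownames(tab)
    desc <- tab[uniq$ligand_id[hit], , drop = FALSE]
    storage.mode(desc) <- "double"
    return(list(descriptors = desc, provider = provider,
                failed = uniq$ligand_id[!hit]))
  }
  rows <- lapply(uniq$smiles, function(s) {
    p <- tryCatch(suppressWarnings({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::prop_OB(mol)
    }), error = function(e) NULL)
    if (!is.data.frame(p) || nrow(p) < 1L) return(NULL)
    unlist(p[1, vapply(p, is.numeric, logical(1)), drop = FALSE])
  })
  ok <- !vapply(rows, is.null, logical(1))
  desc <- do.call(rbind, rows[ok])
  rownames(desc) <- uniq$ligand_id[ok]
  list(descriptors = desc, provider = provider,
       failed = uniq$ligand_id[!ok])
}

#' Assemble the block feature matrix for a set of records
#'
#' Builds the modelling design matrix with one row per record and ordered
#' column blocks [protein | descriptors | fingerprint | mode_flag], where
#' the protein block is the receptor's alignment property-code vector, and
#' the mode flag is 1 for agonists and 0 for antagonists. Total width is
#' L + D + F + 1.
#'
#' @param records bioactivity record data frame.
#' @param codes integer code matrix from [encode_alignment()] (receptor ids
#'   as row names).
#' @param fingerprints 0/1 matrix with ligand ids as row names.
#' @param descriptors numeric matrix with ligand ids as row names; may have
#'   zero columns.
#' @param impute named numeric vector of per-descriptor-column imputation
#'   values for non-finite entries; if \code{NULL}, column medians of the
#'   supplied rows are used and stored in the result for reuse at
#'   prediction time.
#' @return an object of class \code{feature_matrix}: list with \code{x}
#'   (numeric matrix), \code{labels}, \code{records}, \code{provenance}
#'   (data frame: column, block, within_block_index), \code{blocks}
#'   (named block widths) and \code{impute}.
#' @export
assemble_features <- function(records, codes, fingerprints,
                              descriptors = NULL, impute = NULL) {
  if (is.null(descriptors))
    descriptors <- matrix(numeric(0), nrow = nrow(fingerprints), ncol = 0,
                          dimnames = list(rownames(fingerprints), NULL))
  missing_r <- setdiff(unique(records$receptor_id), rownames(codes))
  missing_l <- union(
    setdiff(unique(records$ligand_id), rownames(fingerprints)),
    if (ncol(descriptors) > 0)
      setdiff(unique(records$ligand_id), rownames(descriptors)) else character(0))
  if (length(missing_r) || length(missing_l))
    stop("cannot assemble features; missing receptors: [",
         paste(missing_r, collapse = ", "), "], missing ligands: [",
         paste(missing_l, collapse = ", "), "]")

  prot <- codes[records$receptor_id, , drop = FALSE]
  fp <- fingerprints[records$ligand_id, , drop = FALSE]
  desc <- descriptors[if (ncol(descriptors)) records$ligand_id else
                        rep(1L, nrow(records)), , drop = FALSE]
  if (ncol(desc)) {
    if (is.null(impute))
      impute <- apply(desc, 2, function(col)
        stats::median(col[is.finite(col)]))
    for (j in seq_len(ncol(desc))) {
      bad <- !is.finite(desc[, j])
      if (any(bad)) desc[bad, j] <- impute[j]
    }
  } else impute <- numeric(0)
  mode_flag <- as.numeric(records$mode == "agonist")

  x <- cbind(prot, desc, fp, mode_flag)
  rownames(x) <- records$record_id
  L <- ncol(prot); D <- ncol(desc); F <- ncol(fp)
  colnames(x) <- c(paste0("prot", seq_len(L)),
                   if (D) paste0("desc", seq_len(D)) else character(0),
                   paste0("fp", seq_len(F)), "mode_flag")
  provenance <- data.frame(
    column = seq_len(L + D + F + 1L),
    block = c(rep("protein", L), rep("descriptor", D),
              rep("fingerprint", F), "mode_flag"),
    within_block_index = c(seq_len(L), seq_len(D), seq_len(F), 1L),
    stringsAsFactors = FALSE
  )
  structure(list(x = x, labels = records$label, records = records,
                 provenance = provenance,
                 blocks = c(protein = L, descriptor = D,
                            fingerprint = F, mode_flag = 1L),
                 impute = impute),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Assembled feature matrix: ", nrow(x$x), " records x ", ncol(x$x),
      " features\n  blocks: ",
      paste(names(x$blocks), x$blocks, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Columns of a feature-matrix block
#'
#' @param fm a \code{feature_matrix}.
#' @param block one of \code{"protein"}, \code{"descriptor"},
#'   \code{"fingerprint"}, \code{"mode_flag"}.
#' @return integer vector of column indices of that block.
#' @export
block_columns <- function(fm, block) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm$provenance$column[fm$provenance$block == block]
}

#' Subset a feature matrix to a set of records
#'
#' @param fm a \code{feature_matrix}.
#' @param record_ids record ids to keep, in the given order.
#' @return a \code{feature_matrix} restricted to those rows.
#' @export
subset_records <- function(fm, record_ids) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- match(record_ids, fm$records$record_id)
  if (anyNA(idx))
    stop("unknown record ids: ",
         paste(record_ids[is.na(idx)], collapse = ", "))
  fm$x <- fm$x[idx, , drop = FALSE]
  fm$labels <- fm$labels[idx]
  fm$records <- fm$records[idx, , drop = FALSE]
  fm
}
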