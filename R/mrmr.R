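## Mutual information (bits) between two discrete integer vectors, from
## the plug-in estimate on the joint contingency table.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0L) return(0)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Rank features by minimum-redundancy-maximum-relevance
#'
#' Greedy mRMR ranking of candidate feature columns against the label.
#' The first pick maximizes relevance, the mutual information I(f; y);
#' each subsequent pick maximizes the MID criterion, relevance minus the
#' mean pairwise mutual information with the already-selected features
#' (the MIQ quotient form is available via \code{variant}). Mutual
#' information is estimated on discretized data: integer-valued columns
#' with few levels (e.g. the 0-4 protein property codes) are used as-is,
#' continuous columns and the label are discretized into
#' \code{bins} equal-frequency bins. Ties are broken toward the lowest
#' column index, so the ranking is deterministic.
#'
#' @param fm a \code{feature_matrix}, or a plain numeric matrix.
#' @param labels numeric label vector; defaults to \code{fm$labels} for a
#'   feature matrix.
#' @param m number of features to rank.
#' @param candidates integer vector of candidate column indices. For a
#'   feature matrix the default is the protein and descriptor blocks: the
#'   fingerprint block and the mode flag are protected (always kept,
#'   never ranked).
#' @param variant \code{"MID"} (difference, default) or \code{"MIQ"}
#'   (quotient) redundancy composition.
#' @param bins number of equal-frequency bins for discretizing continuous
#'   columns and the label (default 5).
#' @return an object of class \code{mrmr_ranking}: a data frame with
#'   columns \code{rank}, \code{column}, \code{relevance},
#'   \code{redundancy} (mean MI with previously selected features at the
#'   moment of selection), plus attributes \code{candidates},
#'   \code{protected} and \code{variant}.
#' @export
mrmr_rank <- function(fm, labels = NULL, m, candidates = NULL,
                      variant = c("MID", "MIQ"), bins = 5L) {
  variant <- match.arg(variant)
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    labels <- labels %||% fm$labels
    candidates <- candidates %||%
      c(block_columns(fm, "protein"), block_columns(fm, "descriptor"))
    protected <- setdiff(seq_len(ncol(x)), candidates)
  } else {
    x <- fm
    candidates <- candidates %||% seq_len(ncol(x))
    protected <- setdiff(seq_len(ncol(x)), candidates)
  }
  stopifnot(!is.null(labels), all(is.finite(labels)),
            nrow(x) == length(labels))
  if (m > length(candidates))
    stop("m (", m, ") exceeds the number of candidate columns (",
         length(candidates), ")")

  ydisc <- discretize_ef(labels, bins)
  disc <- lapply(candidates, function(j) {
    col <- x[, j]
    if (all(col == round(col)) && length(unique(col)) <= max(bins, 6L))
      as.integer(col) else discretize_ef(col, bins)
  })
  relevance <- vapply(disc, mutual_information, numeric(1), y = ydisc)

  k <- length(candidates)
  selected <- integer(0)
  red_at_sel <- numeric(0)
  red_sum <- numeric(k)          # sum of MI(candidate, selected so far)
  avail <- rep(TRUE, k)
  for (step in seq_len(m)) {
    n_sel <- length(selected)
    score <- if (n_sel == 0L) relevance
             else if (variant == "MID") relevance - red_sum / n_sel
             else relevance / pmax(red_sum / n_sel, .Machine$double.eps)
    score[!avail] <- -Inf
    ## a feature with zero relevance (e.g. a constant column) must never
    ## be picked while informative candidates remain
    if (any(avail & relevance > 0)) score[relevance <= 0] <- -Inf
    pick <- which.max(score)     # which.max takes the first (lowest index) tie
    selected <- c(selected, pick)
    red_at_sel <- c(red_at_sel, if (n_sel == 0L) 0 else red_sum[pick] / n_sel)
    avail[pick] <- FALSE
    if (step < m) {
      newd <- disc[[pick]]
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(i) mutual_information(disc[[i]], newd),
               numeric(1))
    }
  }
  out <- data.frame(rank = seq_len(m),
                    column = candidates[selected],
                    relevance = relevance[selected],
                    redundancy = red_at_sel)
  attr(out, "candidates") <- candidates
  attr(out, "protected") <- protected
  attr(out, "variant") <- variant
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' Pick the feature budget from a validation-MSE curve
#'
#' Walks the (m, validation MSE) curve in order of increasing m and stops
#' at the smallest m for which the relative MSE improvement of the next
#' point falls below \code{threshold} (default 5\%). If every step keeps
#' improving by at least the threshold, the largest m is returned with a
#' warning.
#'
#' @param curve data frame with columns \code{m} (strictly increasing) and
#'   \code{validation_mse}, or a list of \code{c(m, mse)} pairs.
#' @param threshold relative-improvement threshold (default 0.05).
#' @return the chosen m (integer).
#' @export
choose_feature_budget <- function(curve, threshold = 0.05) {
  if (!is.data.frame(curve))
    curve <- do.call(rbind, lapply(curve, function(p)
      data.frame(m = p[[1]], validation_mse = p[[2]])))
  stopifnot(nrow(curve) >= 2L,
            all(c("m", "validation_mse") %in% names(curve)))
  if (any(diff(curve$m) <= 0)) stop("m must be strictly increasing")
  for (i in seq_len(nrow(curve) - 1L)) {
    imp <- (curve$validation_mse[i] - curve$validation_mse[i + 1L]) /
      curve$validation_mse[i]
    if (imp < threshold) return(as.integer(curve$m[i]))
  }
  warning("validation MSE kept improving by >= ", threshold * 100,
          "% up to the largest m; returning it")
  as.integer(curve$m[nrow(curve)])
}

#' Reduce a feature matrix to the selected features
#'
#' Keeps the top-m mRMR-ranked columns together with the protected
#' fingerprint block and the mode flag. The reported selected-feature
#' count follows the convention that the mode flag is appended but not
#' counted: \code{m + F} for an F-bit fingerprint block.
#'
#' @param fm the \code{feature_matrix} the ranking was computed on.
#' @param ranking an \code{mrmr_ranking}.
#' @param m how many ranked features to keep (defaults to the full
#'   ranking).
#' @return a \code{feature_matrix} restricted to the retained columns, in
#'   original column order, with attributes \code{selected_count}
#'   (= m + F) and \code{selected_columns}.
#' @export
apply_selection <- function(fm, ranking, m = nrow(ranking)) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(ranking, "mrmr_ranking"), m <= nrow(ranking))
  top <- ranking$column[seq_len(m)]
  protected <- c(block_columns(fm, "fingerprint"),
                 block_columns(fm, "mode_flag"))
  keep <- sort(union(top, protected))
  fm$x <- fm$x[, keep, drop = FALSE]
  fm$provenance <- fm$provenance[keep, , drop = FALSE]
  ## column indices refer to the reduced matrix; the original alignment /
  ## block position survives in within_block_index
  fm$provenance$column <- seq_len(nrow(fm$provenance))
  rownames(fm$provenance) <- NULL
  fm$blocks <- c(protein = sum(fm$provenance$block == "protein"),
                 descriptor = sum(fm$provenance$block == "descriptor"),
                 fingerprint = sum(fm$provenance$block == "fingerprint"),
                 mode_flag = sum(fm$provenance$block == "mode_flag"))
  attr(fm, "selected_count") <- m + fm$blocks[["fingerprint"]]
  attr(fm, "selected_columns") <- keep
  fm
}

#' Validation-MSE curve over a feature-budget grid
#'
#' Retrains the model on the top-m features for each m in \code{grid} and
#' records the validation MSE, producing the curve consumed by
#' [choose_feature_budget()].
#'
#' @param fm_train,fm_val training and validation \code{feature_matrix}
#'   objects sharing the same columns (e.g. from [subset_records()]).
#' @param ranking an \code{mrmr_ranking} computed on the training rows.
#' @param grid integer vector of feature budgets m to evaluate.
#' @param specs,folds,seed passed to [stack_ensemble()].
#' @return data frame with columns \code{m} and \code{validation_mse}.
#' @export
budget_curve <- function(fm_train, fm_val, ranking, grid,
                         specs = default_learners(), folds = 5L, seed = 1L) {
  grid <- sort(unique(as.integer(grid)))
  res <- lapply(grid, function(m) {
    tr <- apply_selection(fm_train, ranking, m)
    va <- apply_selection(fm_val, ranking, m)
    fit <- stack_ensemble(tr$x, tr$labels, specs = specs, folds = folds,
                          seed = seed)
    pred <- predict(fit, va$x)
    data.frame(m = m, validation_mse = mean((va$labels - pred)^2))
  })
  do.call(rbind, res)
}
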