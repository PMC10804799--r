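#' Divide the protein block into contiguous equal segments
#'
#' Splits the L alignment columns into k contiguous segments whose sizes
#' differ by at most one: the first (L mod k) segments get
#' floor(L/k) + 1 columns. Seven segments echo the seven-transmembrane
#' architecture of GPCRs.
#'
#' @param L protein block width (number of alignment columns).
#' @param k number of segments (default 7).
#' @return an object of class \code{segment_spec}: data frame with
#'   columns \code{segment}, \code{start}, \code{end} (1-based, inclusive,
#'   over alignment positions) and \code{size}.
#' @export
segment_protein_columns <- function(L, k = 7L) {
  stopifnot(k >= 1L)
  if (L < k) stop("cannot divide ", L, " columns into ", k, " segments")
  base <- L %/% k
  extra <- L %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  end <- cumsum(sizes)
  out <- data.frame(segment = seq_len(k), start = end - sizes + 1L,
                    end = end, size = sizes)
  class(out) <- c("segment_spec", "data.frame")
  out
}

#' Select receptors for interpretation probes
#'
#' Keeps receptors whose validation Pearson correlation against the model
#' is strictly greater than the threshold; probes are only meaningful on
#' receptors the model predicts well.
#'
#' @param report an \code{evaluation_report} grouped by receptor.
#' @param cc_threshold minimum (exclusive) per-receptor CC (default 0.95).
#' @return character vector of receptor ids.
#' @export
select_probe_receptors <- function(report, cc_threshold = 0.95) {
  stopifnot(inherits(report, "evaluation_report"))
  pg <- report$per_group
  pg$group[pg$cc_defined & pg$cc > cc_threshold]
}

## shared machinery: evaluate model on the validation rows of the chosen
## receptors with the protein columns of one segment perturbed
.run_probe <- function(model, fm, split, segments, receptors, probe_kind,
                       seed = NULL, repetitions = 1L,
                       randomize = c("shuffle", "uniform")) {
  randomize <- match.arg(randomize)
  stopifnot(inherits(segments, "segment_spec"))
  recs <- split$validation
  recs <- recs[.filter_mode(recs, model$mode_filter) &
                 recs$receptor_id %in% receptors, , drop = FALSE]
  if (nrow(recs) == 0L)
    stop("no validation records for the selected receptors")
  sub <- subset_records(fm, recs$record_id)
  x0 <- sub$x
  base_pred <- predict(model, x0)
  ridx <- split(seq_len(nrow(recs)), recs$receptor_id)
  baseline <- vapply(ridx, function(i)
    mse_metric(sub$labels[i], base_pred[i]), numeric(1))

  prov <- fm$provenance
  prot <- prov[prov$block == "protein", , drop = FALSE]

  rows <- list()
  for (s in seq_len(nrow(segments))) {
    seg_cols <- prot$column[prot$within_block_index >= segments$start[s] &
                              prot$within_block_index <= segments$end[s]]
    empty <- length(seg_cols) == 0L
    reps <- if (probe_kind == "truncation") 1L else repetitions
    probed_mse_rep <- matrix(NA_real_, nrow = reps, ncol = length(ridx),
                             dimnames = list(NULL, names(ridx)))
    for (r in seq_len(reps)) {
      xp <- x0
      if (!empty) {
        if (probe_kind == "truncation") {
          xp[, seg_cols] <- 0
        } else {
          set.seed(child_seed(seed + r - 1L, paste0("perm", s)))
          for (j in seg_cols) {
            if (randomize == "shuffle")
              xp[, j] <- xp[sample.int(nrow(xp)), j]
            else
              xp[, j] <- sample(0:4, nrow(xp), replace = TRUE)
          }
        }
      }
      pp <- if (empty) base_pred else predict(model, xp)
      probed_mse_rep[r, ] <- vapply(ridx, function(i)
        mse_metric(sub$labels[i], pp[i]), numeric(1))
    }
    probed <- colMeans(probed_mse_rep)
    rows[[s]] <- data.frame(
      probe_kind = probe_kind, segment = s,
      receptor_id = names(ridx),
      n = vapply(ridx, length, integer(1)),
      baseline_mse = as.numeric(baseline),
      probed_mse = as.numeric(probed),
      fold_change = as.numeric(probed / baseline),
      empty_segment = empty,
      seed = if (probe_kind == "permutation") seed else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("probe_report", "data.frame")
  out
}

#' Segment truncation probe
#'
#' For each protein segment in turn, sets all (retained) protein columns
#' of that segment to 0 — the gap code — in the validation rows of the
#' selected receptors, re-evaluates the trained model without refitting,
#' and reports the per-receptor MSE fold change over the unperturbed
#' baseline. A large fold change marks a region the model relies on. A
#' segment with no retained columns (possible after feature selection)
#' is reported with fold change 1 and flagged.
#'
#' @param model a trained \code{mtl_model}.
#' @param fm the \code{feature_matrix} the model was trained from (or its
#'   feature-selected reduction).
#' @param split the \code{dataset_split}.
#' @param segments a \code{segment_spec} over alignment positions.
#' @param receptors receptor ids to probe (e.g. from
#'   [select_probe_receptors()]).
#' @return a \code{probe_report} data frame: probe_kind, segment,
#'   receptor_id, n, baseline_mse, probed_mse, fold_change,
#'   empty_segment, seed.
#' @export
truncation_test <- function(model, fm, split, segments, receptors) {
  .run_probe(model, fm, split, segments, receptors, "truncation")
}

#' Segment permutation probe
#'
#' As [truncation_test()], but instead of zeroing, each protein column in
#' the segment is perturbed: by default it is shuffled across rows
#' (preserving its marginal code frequencies while destroying the
#' receptor-column association); \code{randomize = "uniform"} draws
#' codes uniformly from 0..4 instead. Deterministic under \code{seed};
#' with \code{repetitions > 1} the mean probed MSE over repetitions is
#' reported.
#'
#' @inheritParams truncation_test
#' @param seed integer seed for the shuffles.
#' @param repetitions number of independent shuffles to average
#'   (default 1).
#' @param randomize \code{"shuffle"} (default) or \code{"uniform"}.
#' @return a \code{probe_report} data frame.
#' @export
permutation_test <- function(model, fm, split, segments, receptors,
                             seed = 1L, repetitions = 1L,
                             randomize = c("shuffle", "uniform")) {
  .run_probe(model, fm, split, segments, receptors, "permutation",
             seed = as.integer(seed), repetitions = repetitions,
             randomize = randomize)
}

#' Summarize a probe report per segment
#'
#' @param report a \code{probe_report}.
#' @return data frame with one row per segment: mean baseline MSE, mean
#'   probed MSE and mean fold change over receptors.
#' @export
summarize_probe <- function(report) {
  stopifnot(inherits(report, "probe_report"))
  agg <- lapply(split(report, report$segment), function(d)
    data.frame(segment = d$segment[1],
               n_receptors = nrow(d),
               mean_baseline_mse = mean(d$baseline_mse),
               mean_probed_mse = mean(d$probed_mse),
               mean_fold_change = mean(d$fold_change)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
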