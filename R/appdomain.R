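#' Gap-aware Tanimoto similarity of two property-code vectors
#'
#' Set-style Tanimoto similarity over aligned protein property codes
#' where the gap code 0 marks a missing position. The intersection counts
#' positions where both vectors carry the same non-zero code; each
#' vector's set size is its count of non-zero positions; positions
#' missing in both vectors therefore never contribute. Two all-gap
#' vectors have similarity 0 by convention.
#'
#' @param x,y integer code vectors of equal length (codes 0..4), e.g.
#'   rows of [encode_alignment()] restricted to a column scope.
#' @return similarity in [0, 1].
#' @export
tanimoto_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("code vectors must have equal length (same column scope)")
  inter <- sum(x == y & x != 0)
  nx <- sum(x != 0)
  ny <- sum(y != 0)
  den <- nx + ny - inter
  if (den == 0) return(0)
  inter / den
}

#' Pairwise Tanimoto similarity matrix over receptors
#'
#' Computes the gap-aware Tanimoto similarity for every unordered
#' receptor pair over a chosen column scope: the full protein block, an
#' mRMR-selected subset of alignment positions, or one segment.
#'
#' @param codes integer code matrix (receptors x alignment positions),
#'   from [encode_alignment()].
#' @param columns alignment positions to use (default: all).
#' @param scope free-text label recorded with the result (e.g.
#'   \code{"full-length"}, \code{"selected-features"},
#'   \code{"segment-3"}).
#' @return an object of class \code{similarity_report}: list with
#'   \code{ts} (symmetric matrix, unit diagonal for non-empty vectors),
#'   \code{scope} and \code{columns}.
#' @export
pairwise_similarity_matrix <- function(codes, columns = seq_len(ncol(codes)),
                                       scope = "full-length") {
  stopifnot(is.matrix(codes))
  if (nrow(codes) < 2L) stop("need at least two receptors")
  sub <- codes[, columns, drop = FALSE]
  n <- nrow(sub)
  ts <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- tanimoto_similarity(sub[i, ], sub[j, ])
      ts[i, j] <- v
      ts[j, i] <- v
    }
  }
  structure(list(ts = ts, scope = scope, columns = columns),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  off <- x$ts[lower.tri(x$ts)]
  cat("Pairwise Tanimoto similarity (", x$scope, "): ",
      nrow(x$ts), " receptors over ", length(x$columns),
      " positions\n", sep = "")
  cat(sprintf("  off-diagonal Ts: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Maximum Tanimoto similarity to a reference set
#'
#' For each query receptor, the maximum similarity to any reference
#' receptor; a receptor present in both sets never counts its
#' self-similarity.
#'
#' @param query_codes,reference_codes code matrices with receptor ids as
#'   row names.
#' @param columns alignment positions to use.
#' @return named numeric vector of max Ts per query receptor.
#' @export
max_similarity <- function(query_codes, reference_codes,
                           columns = seq_len(ncol(query_codes))) {
  stopifnot(ncol(query_codes) == ncol(reference_codes))
  q <- query_codes[, columns, drop = FALSE]
  r <- reference_codes[, columns, drop = FALSE]
  vapply(rownames(q), function(id) {
    others <- setdiff(rownames(r), id)
    if (length(others) == 0L)
      stop("reference set contains no receptor other than '", id, "'")
    max(vapply(others, function(o)
      tanimoto_similarity(q[id, ], r[o, ]), numeric(1)))
  }, numeric(1))
}

#' Applicability-domain filter for orphan receptors
#'
#' An orphan receptor is inside the model's applicability domain when its
#' maximum Tanimoto similarity to the training (reference) receptors is
#' strictly greater than the threshold; receptors at or below the
#' threshold are excluded. Operating points of 5\% and 9\% correspond to
#' a permissive and a strict domain.
#'
#' @param orphan_codes code matrix of the orphan receptors.
#' @param reference_codes code matrix of the modelled (training)
#'   receptors.
#' @param threshold similarity threshold in [0, 1] (default 0.05).
#' @param columns alignment positions to use (e.g. the mRMR-selected
#'   protein positions).
#' @return list with data frames \code{retained} and \code{excluded}
#'   (receptor_id, max_ts) and the \code{threshold}.
#' @export
ad_filter <- function(orphan_codes, reference_codes, threshold = 0.05,
                      columns = seq_len(ncol(orphan_codes))) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(reference_codes) == 0L) stop("empty reference set")
  mts <- max_similarity(orphan_codes, reference_codes, columns)
  df <- data.frame(receptor_id = names(mts), max_ts = as.numeric(mts),
                   stringsAsFactors = FALSE)
  keep <- df$max_ts > threshold
  list(retained = df[keep, , drop = FALSE],
       excluded = df[!keep, , drop = FALSE],
       threshold = threshold)
}
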