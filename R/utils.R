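`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Stage-level randomness (alignment, ligands, noise, splits, folds) is
#' driven by named child seeds so that regenerating one stage does not
#' perturb the others. The derivation is a simple deterministic hash of
#' the stage name folded into the 31-bit positive integer range.
#'
#' @param master integer master seed.
#' @param name character stage name.
#' @return an integer seed in [1, 2^31 - 1].
#' @export
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(master) %% 1000003L) * 1009L + h * 31L) %% 2147483629L + 1L
}

## equal-frequency discretization into at most `bins` levels; constant or
## few-valued columns collapse to fewer levels, which is fine for MI
discretize_ef <- function(x, bins = 5L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               na.rm = TRUE, names = FALSE, type = 7))
  findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
}
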