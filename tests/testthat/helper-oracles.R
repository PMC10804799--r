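# Independent oracles shared across test files.

# entropy-based mutual information (bits)
oracle_mi <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  ent(x) + ent(y) - ent(paste(x, y))
}

# brute-force greedy MID selection: the criterion is evaluated over every
# remaining candidate at every step
oracle_mrmr <- function(x, y, m) {
  k <- ncol(x)
  rel <- sapply(seq_len(k), function(j) oracle_mi(x[, j], y))
  sel <- integer(0)
  for (step in seq_len(m)) {
    remaining <- setdiff(seq_len(k), sel)
    informative <- remaining[rel[remaining] > 0]
    pool <- if (length(informative)) informative else remaining
    scores <- sapply(pool, function(j) {
      if (length(sel) == 0) rel[j]
      else rel[j] - mean(sapply(sel, function(s) oracle_mi(x[, j], x[, s])))
    })
    sel <- c(sel, pool[which.max(scores)])
  }
  sel
}

# Tanimoto over explicit (position, code) sets
oracle_ts <- function(x, y) {
  sx <- paste(which(x != 0), x[x != 0])
  sy <- paste(which(y != 0), y[y != 0])
  u <- length(union(sx, sy))
  if (u == 0) return(0)
  length(intersect(sx, sy)) / u
}

# Mann-Whitney U from the rank-sum identity; two-sided p by exhaustive
# enumeration of group assignments of the pooled values
oracle_mannwhitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(length(pooled), n1)
  us <- apply(sets, 2, function(ia) {
    rr <- rank(pooled)
    sum(rr[ia]) - n1 * (n1 + 1) / 2
  })
  list(U = u, p = min(1, 2 * min(mean(us <= u), mean(us >= u))))
}

# the heavy five-seed benchmark, computed once and shared across blocks
.benchmark_cache <- new.env(parent = emptyenv())
benchmark_runs <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- lapply(seeds, run_benchmark_seed)
  .benchmark_cache[[key]]
}
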