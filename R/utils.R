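## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is left untouched. With seed = NULL the expression
## runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

## Derive a stream of child seeds from a master seed, keeping them in the
## 32-bit integer range the base RNG accepts.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

## Split `total` into `n` integers each within [range[1], range[2]]: draw
## uniformly, then walk random indices up or down until the sum matches.
split_total <- function(n, range, total) {
  lo <- range[[1]]; hi <- range[[2]]
  if (total < n * lo || total > n * hi) {
    stop(sprintf("total %d infeasible for %d groups in [%d, %d]",
                 total, n, lo, hi))
  }
  counts <- sample(seq.int(lo, hi), n, replace = TRUE)
  delta <- total - sum(counts)
  while (delta != 0) {
    i <- sample.int(n, 1)
    if (delta > 0 && counts[i] < hi) {
      counts[i] <- counts[i] + 1L; delta <- delta - 1L
    } else if (delta < 0 && counts[i] > lo) {
      counts[i] <- counts[i] - 1L; delta <- delta + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
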