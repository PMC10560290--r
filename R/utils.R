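# internal helpers shared across modules

# stop unless a condition holds; `...` passed to sprintf
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...))
  invisible(TRUE)
}

# coerce a data frame of (chrom, start, end) to an IRanges list split by chrom
ranges_by_chrom <- function(df) {
  split(IRanges::IRanges(start = df$start, end = df$end), df$chrom)
}

# total number of bases of `x` (single interval c(start, end)) covered by the
# normalized interval set `mask` (data frame chrom/start/end), on one chromosome
overlap_bases <- function(chrom, start, end, mask) {
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(m$start, m$end))
  q <- IRanges::IRanges(start, end)
  hits <- IRanges::pintersect(
    IRanges::findOverlapPairs(ir, q)
  )
  sum(IRanges::width(hits))
}

# run `expr` under a local, restored RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# new_tibble-style constructor that stamps a subclass for tidy()/autoplot()
stamp <- function(x, class) {
  class(x) <- c(class, class(x))
  x
}
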