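#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the prior
#' RNG state so sampling inside package functions never perturbs the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# total length of the union of 0-based half-open intervals, clipped to [lo, hi)
interval_union_length <- function(starts, ends, lo = -Inf, hi = Inf) {
  if (length(starts) == 0L) return(0L)
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- s < e
  if (!any(keep)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1L, end = e[keep]))
  sum(IRanges::width(ir))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
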