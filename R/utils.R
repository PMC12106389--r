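#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq phyper p.adjust runif rbeta setNames
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards.  Keeps fixture generation a pure function
# of its spec.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_count_range <- function(x) {
  is.numeric(x) && length(x) == 2 && all(x >= 1) && x[1] <= x[2]
}

# sample() without the length-1 surprise
sample_int <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

semicolon <- function(x) paste(x, collapse = ";")
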