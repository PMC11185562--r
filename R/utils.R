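#' @import methods
#' @importFrom stats rnorm rbinom runif sd p.adjust smooth.spline predict
#' @importFrom utils head read.delim write.table
NULL

## Run `expr` under a temporary RNG state seeded with `seed`; restore the
## caller's RNG afterwards.  seed = NULL means: use the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  x
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

## The 20 canonical amino-acid one-letter codes.
CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Coerce an AAStringSet or character vector to sequences, keeping names.
asNamedSeqs <- function(x) {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- names(x)
  s
}

isCanonical <- function(peptide) {
  all(strsplit(peptide, "")[[1]] %in% CANONICAL_AA)
}
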