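# Small shared helpers.

# Byte-wise (C locale) lexicographic sort, the `LC_ALL=C sort` semantics the
# canonical group ordering is defined by.  method = "radix" sorts character
# data by raw byte value regardless of the session locale.
c_sort <- function(x) sort(x, method = "radix")

c_order <- function(...) order(..., method = "radix")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Split text into lines without dropping a trailing empty line explicitly;
# strsplit() on "\n" is what every format reader here builds on.
split_lines <- function(text) {
  strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
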