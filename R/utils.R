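# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# round() in R is half-even; reported percentages use half-up at `digits`.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Minimal union-find for single-linkage clustering of pairwise links.
uf_components <- function(n, links) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (length(links)) for (k in seq_len(nrow(links))) {
    a <- find(links[k, 1]); b <- find(links[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)
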