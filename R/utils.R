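# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.  All randomized
# operations in the package route through this so that a seed argument
# never perturbs (and is never perturbed by) the global RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# canonical form of a state label: trimmed, case-folded
canon_label <- function(x) tolower(trimws(as.character(x)))

# Match raw labels against declared states, case-insensitively after
# trimming.  Returns integer state indices; NA stays NA; invalid labels
# yield NA with attribute "bad" holding their positions.
match_states <- function(x, states) {
  idx <- match(canon_label(x), canon_label(states))
  idx[is.na(x)] <- NA_integer_
  bad <- which(!is.na(x) & is.na(idx))
  if (length(bad)) attr(idx, "bad") <- bad
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
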