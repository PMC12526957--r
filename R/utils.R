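# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Shift a matrix by (dr, dc), padding with `fill`. Used by the thinning and
# feature code; dr > 0 moves content down (so the value at [r, c] becomes the
# neighbour originally at [r - dr, c - dc]).
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

# Half-open equal bands over 0..(n-1): band i covers [i*h, (i+1)*h) with
# h = floor(n/L); the last band absorbs the remainder. Returns the 1-based
# band index for each 0-based position, or NA where h == 0 maps everything
# to the final band.
band_index <- function(pos0, n, L) {
  h <- n %/% L
  if (h == 0L) {
    return(rep.int(L, length(pos0)))
  }
  idx <- pos0 %/% h + 1L
  idx[idx > L] <- L
  idx
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min),
          class = "rhizo_parameter_error")
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
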