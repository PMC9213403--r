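# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derivation; stays inside 32-bit signed range.
derive_seed <- function(base, k) {
  m <- 2147483563
  s <- (as.double(base) %% m + as.double(k) * 48271) %% m
  as.integer(s) + 1L
}

# Clamp to [0,255] and round to the 8-bit grid (images are stored as
# integer-valued doubles in 0..255).
clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

# distance-from-point field over an h x w grid, in pixels
dist_field <- function(h, w, center) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}

# logical dilation with a disc brush (odd size)
dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  size <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}
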