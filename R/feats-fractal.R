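# pairwise block reduction for power-of-two factors (fast path)
.block_reduce_pow2 <- function(A, s, f) {
  k <- as.integer(round(log2(s)))
  for (i in seq_len(k)) {
    o <- seq(1, nrow(A), by = 2)
    A <- f(A[o, , drop = FALSE], A[o + 1, , drop = FALSE])
    o <- seq(1, ncol(A), by = 2)
    A <- f(A[, o, drop = FALSE], A[, o + 1, drop = FALSE])
  }
  A
}

.block_reduce <- function(A, s, which = c("max", "min")) {
  which <- match.arg(which)
  if (s == 1) return(A)
  if (abs(log2(s) - round(log2(s))) < 1e-9) {
    f <- if (which == "max") pmax else pmin
    return(.block_reduce_pow2(A, s, f))
  }
  g <- rep(seq_len(nrow(A) / s), each = s)
  f <- get(which)
  red <- apply(array(A, c(s, nrow(A) / s, ncol(A))), c(2, 3), f)
  t(apply(array(t(red), c(s, ncol(A) / s, nrow(A) / s)), c(2, 3), f))
}

.block_sum <- function(A, s) {
  if (s == 1) return(A)
  g <- rep(seq_len(nrow(A) / s), each = s)
  B <- rowsum(A, g, reorder = FALSE)
  h <- rep(seq_len(ncol(A) / s), each = s)
  t(rowsum(t(B), h, reorder = FALSE))
}

.fd_slope <- function(sizes, counts) {
  keep <- counts > 0
  if (sum(keep) < 2) return(0)
  x <- -log(sizes[keep])
  y <- log(counts[keep])
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Differential box-counting fractal dimension
#'
#' Treats gray levels as surface height. For box size `s` the gray axis is
#' partitioned into boxes of height `h = s * (gray_range + 1) / side` (with
#' `gray_range = 255` for 8-bit images); each `s x s` grid cell contributes
#' `n = ceil(max/h) - ceil(min/h) + 1` boxes, `N(s)` is the sum over cells,
#' and the dimension is the least-squares slope of `log N(s)` against
#' `log(1/s)`. A constant image yields exactly 2.
#'
#' @param gray Square numeric matrix (0..255); side must be divisible by
#'   every box size.
#' @param box_sizes Integer box sizes; default powers of 2 in
#'   `[2, min(side/4, 32)]`. At least 3 sizes are required.
#' @param gray_levels Number of gray levels spanned by the surface
#'   (default 256).
#' @return The dimension estimate, with attributes `sizes` and `counts`.
#' @export
dbc_fd <- function(gray, box_sizes = NULL, gray_levels = 256) {
  if (!is.matrix(gray) || nrow(gray) != ncol(gray)) {
    stop_param("gray", "must be a square matrix")
  }
  side <- nrow(gray)
  if (is.null(box_sizes)) {
    box_sizes <- 2^(1:30)
    box_sizes <- box_sizes[box_sizes <= min(side / 4, 32)]
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3) stop("need at least 3 usable box sizes", call. = FALSE)
  if (any(side %% box_sizes != 0)) {
    stop_param("box_sizes", "every size must divide the image side")
  }
  counts <- vapply(box_sizes, function(s) {
    h <- s * gray_levels / side
    mx <- .block_reduce(gray, s, "max")
    mn <- .block_reduce(gray, s, "min")
    sum(ceiling(mx / h) - ceiling(mn / h) + 1)
  }, numeric(1))
  structure(.fd_slope(box_sizes, counts), sizes = box_sizes, counts = counts)
}

#' Binary box-counting fractal dimension
#'
#' Counts, for each box size, the number of grid cells containing at least
#' one foreground pixel; the dimension is the least-squares slope of
#' `log N(s)` against `log(1/s)`.
#'
#' @param bin Square logical (or 0/1) matrix; side divisible by all sizes.
#' @param box_sizes Integer box sizes (>= 3 of them); default powers of 2 in
#'   `[1, side/4]` capped at 32.
#' @return The dimension estimate, with attributes `sizes` and `counts`.
#' @examples
#' box_count_fd(matrix(TRUE, 64, 64))  # filled plane: ~2
#' @export
box_count_fd <- function(bin, box_sizes = NULL) {
  if (!is.matrix(bin) || nrow(bin) != ncol(bin)) {
    stop_param("bin", "must be a square matrix")
  }
  side <- nrow(bin)
  if (is.null(box_sizes)) {
    box_sizes <- 2^(0:30)
    box_sizes <- box_sizes[box_sizes <= min(side / 4, 32)]
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3) stop("need at least 3 usable box sizes", call. = FALSE)
  if (any(side %% box_sizes != 0)) {
    stop_param("box_sizes", "every size must divide the image side")
  }
  b <- (bin > 0) * 1
  if (sum(b) == 0) {
    return(structure(0, sizes = box_sizes, counts = rep(0, length(box_sizes))))
  }
  counts <- vapply(box_sizes, function(s) sum(.block_sum(b, s) > 0), numeric(1))
  structure(.fd_slope(box_sizes, counts), sizes = box_sizes, counts = counts)
}

#' Fractal feature block
#'
#' Crops the masked gray image to a centered square whose side is a multiple
#' of 32 (16 for small inputs), fills outside-mask pixels with the rounded
#' masked mean (making the block invariant to anything outside the field of
#' view), and computes differential box-counting dimensions over the full
#' scale range and its fine/coarse halves, plus the binary box-count
#' dimension of the Otsu-thresholded foreground.
#'
#' @inheritParams glcm_features
#' @param box_sizes Optional explicit box sizes passed to [dbc_fd()].
#' @return Named numeric vector `fd_dbc`, `fd_dbc_fine`, `fd_dbc_coarse`,
#'   `fd_box_binary`.
#' @export
fractal_features <- function(gray, mask = NULL, box_sizes = NULL) {
  if (!is.matrix(gray)) stop_param("gray", "must be a matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  v <- gray[mask]
  if (length(v) == 0) stop("empty mask", call. = FALSE)
  fill <- round(mean(v))
  g2 <- gray
  g2[!mask] <- fill
  m2 <- mask

  side0 <- min(dim(g2))
  unit <- if (side0 >= 128) 32L else 16L
  side <- unit * (side0 %/% unit)
  if (side < 3 * unit / 2) stop("image too small for fractal analysis", call. = FALSE)
  r0 <- floor((nrow(g2) - side) / 2) + 1L
  c0 <- floor((ncol(g2) - side) / 2) + 1L
  g2 <- g2[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
  m2 <- m2[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]

  sizes <- box_sizes
  if (is.null(sizes)) {
    sizes <- 2^(1:30)
    sizes <- sizes[sizes <= min(side / 4, 32)]
  }
  fd_all <- dbc_fd(g2, sizes)
  n <- length(sizes)
  fine <- if (n >= 5) sizes[1:ceiling(n / 2)] else sizes
  coarse <- if (n >= 5) sizes[floor((n + 1) / 2):n] else sizes
  fd_fine <- dbc_fd(g2, fine)
  fd_coarse <- dbc_fd(g2, coarse)

  inside <- g2[m2]
  th <- if (length(unique(inside)) > 1) {
    EBImage::otsu(g2 / 255, range = c(0, 1)) * 255
  } else fill
  bin <- (g2 > th) & m2
  fd_bin <- box_count_fd(bin, sizes)

  c(fd_dbc = as.numeric(fd_all),
    fd_dbc_fine = as.numeric(fd_fine),
    fd_dbc_coarse = as.numeric(fd_coarse),
    fd_box_binary = as.numeric(fd_bin))
}
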