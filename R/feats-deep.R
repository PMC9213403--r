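# cached frequency-domain oriented Gaussian filter bank, keyed by image side
.filterbank_cache <- new.env(parent = emptyenv())

.filterbank <- function(side, scales = c(2, 4, 8, 16), n_orient = 8) {
  key <- paste(side, paste(scales, collapse = ","), n_orient, sep = "|")
  if (!is.null(.filterbank_cache[[key]])) return(.filterbank_cache[[key]])
  fr <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  fu <- matrix(fr, side, side)              # row-frequency
  fv <- matrix(fr, side, side, byrow = TRUE)  # column-frequency
  rho <- sqrt(fu^2 + fv^2)
  theta <- atan2(fu, fv)
  bank <- list()
  for (s in scales) {
    f0 <- 1 / (4 * s)  # center frequency in cycles/pixel
    radial <- exp(-((rho - f0)^2) / (2 * (f0 / 2)^2))
    for (o in seq_len(n_orient) - 1) {
      ang <- o * pi / n_orient
      dth <- atan2(sin(theta - ang), cos(theta - ang))
      dth <- pmin(abs(dth), pi - abs(dth))  # real filters: +-pi symmetric
      angular <- exp(-(dth^2) / (2 * (pi / (2 * n_orient))^2))
      bank[[sprintf("s%g_o%d", s, o)]] <- radial * angular
    }
  }
  .filterbank_cache[[key]] <- bank
  bank
}

#' Deterministic softmax embedding from an oriented filter bank
#'
#' Computes a fixed-length probability vector from a standardized RGB array:
#' multi-scale oriented band energies (a frequency-domain Gaussian filter
#' bank, 4 scales x 8 orientations per channel, evaluated via Parseval's
#' identity) plus raw channel means and standard deviations, projected
#' through a fixed-seed random linear map and a softmax. The output mimics
#' the shape of a 1000-way classification-layer activation: all entries are
#' non-negative and sum to 1, and the map is a pure function of the input.
#'
#' This embedding is a deterministic, training-free image descriptor; it is
#' selected with `backbone = "filterbank"` and is the only backbone bundled
#' with the package.
#'
#' @param rgb A side x side x 3 standardized array (see [preprocess()]).
#' @param backbone Backbone identifier; only `"filterbank"` is available.
#' @param n_out Output length (default 1000).
#' @return Named numeric vector `deep_0001` ... of length `n_out`.
#' @export
deep_features <- function(rgb, backbone = "filterbank", n_out = 1000) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3 || dim(rgb)[1] != dim(rgb)[2]) {
    stop_param("rgb", "must be a square side x side x 3 array")
  }
  if (!identical(backbone, "filterbank")) {
    stop(sprintf("backbone '%s' is not available; use 'filterbank'", backbone),
         call. = FALSE)
  }
  side <- dim(rgb)[1]
  bank <- .filterbank(side)
  feats <- numeric(0)
  for (ch in 1:3) {
    Fc <- stats::fft(rgb[, , ch])
    p <- Mod(Fc)^2
    e <- vapply(bank, function(G) sum(p * G^2) / side^4, numeric(1))
    feats <- c(feats, e)
  }
  feats <- c(feats,
             vapply(1:3, function(ch) mean(rgb[, , ch]^3), numeric(1)),
             vapply(1:3, function(ch) mean(abs(rgb[, , ch])), numeric(1)))
  fv <- log1p(pmax(feats, 0) * 1e4)
  fv <- (fv - mean(fv)) / max(stats::sd(fv), 1e-9)
  d <- length(fv)
  W <- with_seed(91251L, matrix(stats::rnorm(n_out * d), n_out, d))
  z <- as.numeric(W %*% fv) / sqrt(d)
  z <- z - max(z)
  out <- exp(z) / sum(exp(z))
  names(out) <- sprintf("deep_%04d", seq_len(n_out))
  out
}
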