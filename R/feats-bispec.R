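# principal-domain cell indices for segment length n (0-based frequencies):
# 0 <= f2 <= f1, f1 + f2 <= n/2
.bispec_domain <- function(n) {
  half <- n %/% 2
  f1 <- integer(0); f2 <- integer(0)
  for (a in 0:half) {
    b <- 0:min(a, half - a)
    f1 <- c(f1, rep.int(a, length(b)))
    f2 <- c(f2, b)
  }
  list(f1 = f1, f2 = f2)
}

.hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Bispectrum of a 1-D profile
#'
#' Estimates the bispectrum `B(f1, f2) = X(f1) X(f2) X*(f1 + f2)` on the
#' principal domain by averaging over Hann-windowed, mean-removed segments
#' with 50% overlap (Welch-style direct estimator). The bispectrum is the
#' third-order spectrum and is sensitive to phase coupling between frequency
#' pairs, which broadband pathology-driven structure perturbs.
#'
#' @param x Numeric profile.
#' @param seg_len Segment length (default 64); `x` must be at least this long.
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A list with complex `B` and integer vectors `f1`, `f2`.
#' @export
bispectrum_profile <- function(x, seg_len = 64, overlap = 0.5) {
  L <- length(x)
  if (L < seg_len) stop("profile shorter than segment length", call. = FALSE)
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, L - seg_len + 1L, by = hop)
  dom <- .bispec_domain(seg_len)
  w <- .hann(seg_len)
  i1 <- dom$f1 + 1L
  i2 <- dom$f2 + 1L
  i3 <- dom$f1 + dom$f2 + 1L
  B <- complex(length(i1))
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    B <- B + X[i1] * X[i2] * Conj(X[i3])
  }
  list(B = B / length(starts), f1 = dom$f1, f2 = dom$f2)
}

# entropy summaries of one estimated bispectrum
.bispec_summaries <- function(B, nphase_bins = 16) {
  A <- Mod(B)
  tot <- sum(A)
  nc <- length(A)
  if (!is.finite(tot) || tot < 1e-12) {
    return(c(p1 = 0, p2 = 0, mean_mag = 0, phase_entropy = 0))
  }
  p <- A / tot
  p1 <- -sum(p[p > 0] * log(p[p > 0])) / log(nc)
  q <- A^2 / sum(A^2)
  p2 <- -sum(q[q > 0] * log(q[q > 0])) / log(nc)
  ph <- Arg(B[A > 1e-12])
  pe <- if (length(ph) == 0) 0 else {
    h <- tabulate(pmin(as.integer(floor((ph + pi) / (2 * pi) * nphase_bins)) + 1L,
                       nphase_bins),
                  nbins = nphase_bins)
    f <- h / sum(h)
    -sum(f[f > 0] * log(f[f > 0])) / log(nphase_bins)
  }
  c(p1 = p1, p2 = p2, mean_mag = tot / nc, phase_entropy = pe)
}

# masked 1-D profiles: row means, column means, 8 radial diameters
.image_profiles <- function(gray, mask, center, radius) {
  g <- gray
  g[!mask] <- NA
  prof <- list(
    row = rowMeans(g, na.rm = TRUE),
    col = colMeans(g, na.rm = TRUE)
  )
  prof <- lapply(prof, function(p) p[is.finite(p)])
  h <- nrow(gray); w <- ncol(gray)
  t_steps <- seq(-radius, radius, by = 1)
  for (k in 0:7) {
    th <- k * pi / 8
    r <- round(center[1] + t_steps * sin(th))
    c <- round(center[2] + t_steps * cos(th))
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    idx <- cbind(r[ok], c[ok])
    val <- gray[idx]
    val <- val[mask[idx]]
    prof[[paste0("rad", k)]] <- val
  }
  prof
}

#' Bispectral (higher-order spectra) feature block
#'
#' Extracts 1-D profiles from the masked gray image (row means, column means
#' and 8 radial diameters through the field-of-view center), estimates each
#' profile's bispectrum with [bispectrum_profile()], and summarizes it with
#' four quantities: the normalized bispectral entropy P1 (Shannon entropy of
#' `|B|` normalized to a distribution, divided by `log` of the number of
#' principal-domain cells), the squared-magnitude entropy P2, the mean
#' bispectral magnitude, and the entropy of the bispectral phase histogram.
#' Entropies of an all-zero bispectrum are defined as 0.
#'
#' Profiles shorter than the segment length are skipped (their features are
#' zero-filled so the block layout is identical across images); if every
#' profile is too short an error is raised.
#'
#' @inheritParams glcm_features
#' @param center FOV center `c(row, col)`; defaults to the mask centroid.
#' @param radius FOV radius in pixels; defaults to the equivalent-area radius.
#' @param seg_len Segment length for the bispectrum estimator (default 64).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Named numeric vector: 4 summaries for each of the 10 profiles.
#' @export
bispectral_features <- function(gray, mask = NULL, center = NULL, radius = NULL,
                                seg_len = 64, overlap = 0.5) {
  if (!is.matrix(gray)) stop_param("gray", "must be a matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  if (is.null(center)) {
    idx <- which(mask, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  if (is.null(radius)) radius <- sqrt(sum(mask) / pi)
  prof <- .image_profiles(gray, mask, center, radius)
  out <- numeric(0)
  n_ok <- 0L
  for (nm in names(prof)) {
    p <- prof[[nm]]
    feats <- if (length(p) >= seg_len) {
      n_ok <- n_ok + 1L
      bs <- bispectrum_profile(p, seg_len = seg_len, overlap = overlap)
      .bispec_summaries(bs$B)
    } else {
      c(p1 = 0, p2 = 0, mean_mag = 0, phase_entropy = 0)
    }
    names(feats) <- paste("bis", nm, names(feats), sep = "_")
    out <- c(out, feats)
  }
  if (n_ok == 0L) {
    stop("all profiles shorter than the segment length", call. = FALSE)
  }
  out
}
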