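#' Gray-level co-occurrence texture features
#'
#' Quantizes the masked gray values into `levels` equal-width bins over the
#' masked range, builds one directed co-occurrence matrix per pixel offset,
#' and summarizes each with the standard Haralick-style statistics: contrast
#' `sum((i-j)^2 p)`, correlation `sum((i-mu_i)(j-mu_j)p)/(sd_i sd_j)`, energy
#' `sum(p^2)`, homogeneity `sum(p/(1+|i-j|))` and entropy `-sum(p log2 p)`
#' (with `0 log 0 = 0`). First-order statistics of the masked histogram
#' (mean, variance, skewness, kurtosis, entropy) are appended once.
#'
#' Only pixel pairs with both members inside the mask contribute. On a
#' constant image the correlation is defined as 0 (degenerate sd).
#'
#' @param gray Numeric matrix of gray values.
#' @param mask Logical matrix; NULL means all pixels.
#' @param levels Number of quantization bins (default 16).
#' @param offsets List of `c(dr, dc)` integer offsets; defaults to the four
#'   distance-1 directions (0,1), (1,0), (1,1), (1,-1).
#' @return A named numeric vector: five statistics per offset plus the five
#'   first-order statistics.
#' @examples
#' g <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' glcm_features(g, levels = 2, offsets = list(c(0, 1)))
#' @export
glcm_features <- function(gray, mask = NULL, levels = 16,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  if (!is.matrix(gray)) stop_param("gray", "must be a matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  v <- gray[mask]
  if (length(v) == 0) stop("empty mask", call. = FALSE)
  rng <- range(v)
  span <- diff(rng)
  q <- if (span == 0) {
    matrix(0L, nrow(gray), ncol(gray))
  } else {
    matrix(pmin(as.integer(floor((gray - rng[1]) / (span * (1 + 1e-12)) * levels)),
                levels - 1L),
           nrow(gray), ncol(gray))
  }
  q[q < 0L] <- 0L

  out <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    h <- nrow(gray); w <- ncol(gray)
    rA <- (1 + max(0, -dr)):(h - max(0, dr))
    cA <- (1 + max(0, -dc)):(w - max(0, dc))
    qa <- q[rA, cA, drop = FALSE]
    qb <- q[rA + dr, cA + dc, drop = FALSE]
    ok <- mask[rA, cA, drop = FALSE] & mask[rA + dr, cA + dc, drop = FALSE]
    counts <- tabulate(qa[ok] * levels + qb[ok] + 1L, nbins = levels^2)
    tot <- sum(counts)
    stats5 <- if (tot == 0) {
      c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0, entropy = 0)
    } else {
      p <- matrix(counts / tot, levels, levels, byrow = TRUE)  # p[i+1, j+1]
      i <- matrix(0:(levels - 1), levels, levels)
      j <- t(i)
      pi_ <- rowSums(p)
      pj_ <- colSums(p)
      mu_i <- sum((0:(levels - 1)) * pi_)
      mu_j <- sum((0:(levels - 1)) * pj_)
      sd_i <- sqrt(sum(((0:(levels - 1)) - mu_i)^2 * pi_))
      sd_j <- sqrt(sum(((0:(levels - 1)) - mu_j)^2 * pj_))
      corr <- if (sd_i > 0 && sd_j > 0) {
        sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
      } else 0
      pos <- p > 0
      c(contrast = sum((i - j)^2 * p),
        correlation = corr,
        energy = sum(p^2),
        homogeneity = sum(p / (1 + abs(i - j))),
        entropy = -sum(p[pos] * log2(p[pos])))
    }
    tag <- sprintf("glcm_%d_%s", dr, ifelse(dc < 0, paste0("m", -dc), dc))
    names(stats5) <- paste(tag, names(stats5), sep = "_")
    out <- c(out, stats5)
  }

  m1 <- mean(v)
  m2 <- mean((v - m1)^2)
  sk <- if (m2 > 0) mean((v - m1)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - m1)^4) / m2^2 else 0
  qv <- q[mask]
  f <- tabulate(qv + 1L, nbins = levels)
  f <- f / sum(f)
  fo_ent <- -sum(f[f > 0] * log2(f[f > 0]))
  c(out,
    fo_mean = m1, fo_variance = m2, fo_skewness = sk,
    fo_kurtosis = ku, fo_entropy = fo_ent)
}
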