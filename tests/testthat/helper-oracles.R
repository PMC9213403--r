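# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# GLCM statistics by explicit pixel-pair enumeration
oracle_glcm <- function(gray, mask, levels, offset) {
  v <- gray[mask]
  rng <- range(v)
  span <- diff(rng)
  qz <- function(g) {
    if (span == 0) return(0L)
    min(as.integer(floor((g - rng[1]) / (span * (1 + 1e-12)) * levels)), levels - 1L)
  }
  P <- matrix(0, levels, levels)
  h <- nrow(gray); w <- ncol(gray)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (!mask[r, c] || !mask[r2, c2]) next
      i <- qz(gray[r, c]); j <- qz(gray[r2, c2])
      P[i + 1, j + 1] <- P[i + 1, j + 1] + 1
    }
  }
  P <- P / sum(P)
  idx <- 0:(levels - 1)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mui <- sum(idx * pi_); muj <- sum(idx * pj_)
  sdi <- sqrt(sum((idx - mui)^2 * pi_)); sdj <- sqrt(sum((idx - muj)^2 * pj_))
  con <- 0; hom <- 0; ent <- 0; ene <- 0; cor <- 0
  for (i in idx) {
    for (j in idx) {
      p <- P[i + 1, j + 1]
      con <- con + (i - j)^2 * p
      hom <- hom + p / (1 + abs(i - j))
      ene <- ene + p^2
      if (p > 0) ent <- ent - p * log2(p)
      if (sdi > 0 && sdj > 0) cor <- cor + (i - mui) * (j - muj) * p / (sdi * sdj)
    }
  }
  c(contrast = con, correlation = cor, energy = ene, homogeneity = hom,
    entropy = ent)
}

# AUC as the Mann-Whitney pairwise probability, ties counted one half
oracle_auc <- function(y_true, scores, positive) {
  pos <- which(y_true == positive)
  neg <- which(y_true != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# bispectrum by explicit DFT sums and triple products over the principal domain
oracle_bispectrum <- function(x, seg_len, overlap = 0.5) {
  hop <- round(seg_len * (1 - overlap))
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  k <- 0:(seg_len - 1)
  win <- 0.5 * (1 - cos(2 * pi * k / (seg_len - 1)))
  dft <- function(s, f) sum(s * exp(-2i * pi * f * k / seg_len))
  half <- seg_len %/% 2
  cells <- list()
  for (a in 0:half) for (b in 0:min(a, half - a)) cells[[length(cells) + 1]] <- c(a, b)
  B <- rep(0 + 0i, length(cells))
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    for (ci in seq_along(cells)) {
      a <- cells[[ci]][1]; b <- cells[[ci]][2]
      B[ci] <- B[ci] + dft(seg, a) * dft(seg, b) * Conj(dft(seg, a + b))
    }
  }
  B / length(starts)
}

oracle_bispec_p1 <- function(B) {
  A <- Mod(B)
  p <- A / sum(A)
  -sum(p[p > 0] * log(p[p > 0])) / log(length(A))
}

# Sierpinski carpet as a logical matrix of side 3^k
sierpinski_carpet <- function(k) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(k)) {
    s <- nrow(m)
    out <- matrix(FALSE, 3 * s, 3 * s)
    for (bi in 0:2) {
      for (bj in 0:2) {
        if (bi == 1 && bj == 1) next
        out[bi * s + seq_len(s), bj * s + seq_len(s)] <- m
      }
    }
    m <- out
  }
  m
}

clamp8_ref <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

# small deterministic test image bundle
fixture_image <- function(seed = 1, size = 128) {
  render_fundus(scene_params(image_size = size, rng_seed = seed))
}
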