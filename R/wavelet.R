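# Periodized discrete wavelet transform with Daubechies-4 (8-tap) filters,
# used for detail-coefficient soft thresholding. Filters are the standard
# orthonormal db4 scaling coefficients (sum = sqrt(2), unit energy).
.db4_h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)

.db4_g <- rev(.db4_h) * (-1)^(seq_along(.db4_h) - 1)

.dwt_step <- function(x) {
  n <- length(x)
  n2 <- n %/% 2L
  L <- length(.db4_h)
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in 0:(L - 1L)) {
    idx <- (base + m) %% n + 1L
    a <- a + .db4_h[m + 1L] * x[idx]
    d <- d + .db4_g[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d) {
  n2 <- length(a)
  n <- 2L * n2
  y <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in 0:(length(.db4_h) - 1L)) {
    idx <- (base + m) %% n + 1L
    y[idx] <- y[idx] + .db4_h[m + 1L] * a + .db4_g[m + 1L] * d
  }
  y
}

# Multi-level periodized DWT; length(x) must be divisible by 2^level.
.dwt <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- .dwt_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  list(a = a, d = details)
}

.idwt <- function(w) {
  a <- w$a
  for (l in rev(seq_along(w$d))) a <- .idwt_step(a, w$d[[l]])
  a
}

.soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)

# Wavelet denoising of a plain numeric vector: symmetric end-padding to a
# multiple of 2^level, db4 decomposition, soft universal thresholding of all
# detail levels (sigma from the MAD of the finest details), reconstruction.
# Translation-invariant (cycle-spinning) averaging over circular shifts
# suppresses the pseudo-Gibbs smearing that a single-basis soft threshold
# leaves around sharp waveform features such as the pulse foot.
wt_denoise <- function(x, level, n_shifts = 16L) {
  n <- length(x)
  if (n < 2^level)
    stop("signal too short for decomposition level ", level)
  block <- 2^level
  pad <- (block - n %% block) %% block
  xp <- if (pad > 0) c(x, rev(tail(x, pad))) else x
  np <- length(xp)
  denoise_once <- function(z) {
    w <- .dwt(z, level)
    sigma <- mad(w$d[[1]], center = 0)
    thr <- sigma * sqrt(2 * log(np))
    w$d <- lapply(w$d, .soft_threshold, thr = thr)
    .idwt(w)
  }
  acc <- numeric(np)
  for (s in seq_len(n_shifts) - 1L) {
    shifted <- if (s == 0) xp else c(xp[-seq_len(s)], xp[seq_len(s)])
    den <- denoise_once(shifted)
    acc <- acc + if (s == 0) den else c(tail(den, s), head(den, np - s))
  }
  (acc / n_shifts)[seq_len(n)]
}
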