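# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# derive a child seed from a base seed and a stream index, kept < 2^31
derive_seed <- function(base, index) {
  as.integer((as.double(base) * 1009 + as.double(index) * 7919) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# centred FFT frequency coordinates in cycles/sample for length n,
# in fftshift-free (DC-first) order matching stats::fft
fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / n
}

# gaussian-filtered white noise field (periodic), unit sd after filtering
smooth_noise_field <- function(nr, nc, corr_px) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_px <= 0) return(z)
  fy <- fft_freq(nr)
  fx <- fft_freq(nc)
  g <- exp(-2 * pi^2 * corr_px^2 *
             (outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)))
  zf <- fft(z) * g
  out <- Re(fft(zf, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

# simple box-filtered local standard deviation, used to find cell-free pixels
local_sd <- function(x, half = 2L) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- function(m) {
    m2 <- m[c(rep(1L, half), seq_len(nr), rep(nr, half)), , drop = FALSE]
    m2[, c(rep(1L, half), seq_len(nc), rep(nc, half)), drop = FALSE]
  }
  xp <- pad(x)
  k <- 2L * half + 1L
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
  for (di in seq_len(k) - 1L) {
    for (dj in seq_len(k) - 1L) {
      blk <- xp[di + seq_len(nr), dj + seq_len(nc)]
      s <- s + blk
      s2 <- s2 + blk^2
    }
  }
  n <- k * k
  v <- pmax(s2 / n - (s / n)^2, 0)
  sqrt(v)
}

# pixels likely free of cells: lowest local variability quantile
background_mask <- function(phase, frac = 0.25) {
  ls <- local_sd(phase)
  thr <- stats::quantile(ls, frac)
  m <- ls <= thr
  if (!any(m)) {
    m <- matrix(FALSE, nrow(phase), ncol(phase))
    b <- 8L
    m[c(seq_len(b), nrow(m) - seq_len(b) + 1L), ] <- TRUE
    m[, c(seq_len(b), ncol(m) - seq_len(b) + 1L)] <- TRUE
  }
  m
}
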