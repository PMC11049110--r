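# shared fixtures and independent oracles, all built in code at test time

small_config <- function(n = 128, frames = 3, ...) {
  optical_config(pixel_count_x = n, pixel_count_y = n,
                 frames_per_stack = frames, ...)
}

# native-pitch config (same pixel pitch as the 512 px instrument default)
native_pitch_config <- function(n = 256, frames = 1) {
  optical_config(pixel_count_x = n, pixel_count_y = n,
                 fov_x = 405 * n / 512, fov_y = 538 * n / 512,
                 frames_per_stack = frames)
}

wrap_to_pi <- function(x) atan2(sin(x), cos(x))

border_rmse <- function(a, b, border = 16L) {
  stopifnot(all(dim(a) == dim(b)))
  d <- a - b
  d <- d - mean(d)
  i <- (border + 1):(nrow(a) - border)
  j <- (border + 1):(ncol(a) - border)
  sqrt(mean(d[i, j]^2))
}

# brute-force non-flat morphology: an independent pure-R implementation of
# the definition (min/max over the element support, borders ignored)
bf_shift <- function(img, di, dj, fill) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  src_i <- seq_len(nr) + di
  src_j <- seq_len(nc) + dj
  ok_i <- src_i >= 1 & src_i <= nr
  ok_j <- src_j >= 1 & src_j <= nc
  out[ok_i, ok_j] <- img[src_i[ok_i], src_j[ok_j]]
  out
}

bf_erode <- function(img, se) {
  k <- (nrow(se) - 1) / 2
  acc <- matrix(Inf, nrow(img), ncol(img))
  for (a in seq_len(nrow(se))) {
    for (b in seq_len(ncol(se))) {
      h <- se[a, b]
      if (is.na(h)) next
      acc <- pmin(acc, bf_shift(img, a - k - 1, b - k - 1, Inf) - h)
    }
  }
  acc
}

bf_dilate <- function(img, se) {
  k <- (nrow(se) - 1) / 2
  acc <- matrix(-Inf, nrow(img), ncol(img))
  for (a in seq_len(nrow(se))) {
    for (b in seq_len(ncol(se))) {
      h <- se[a, b]
      if (is.na(h)) next
      acc <- pmax(acc, bf_shift(img, -(a - k - 1), -(b - k - 1), -Inf) + h)
    }
  }
  acc
}

bf_opening <- function(img, se) bf_dilate(bf_erode(img, se), se)

# 4PL evaluated directly (independent of the package's truth object)
four_pl <- function(d, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (d / ec50)^hill)
}
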