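## Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched, so generators are reproducible without side effects.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# FFT sample frequencies (cycles per unit), numpy convention.
fftFreq <- function(n, d = 1) {
  c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# Sliding-window maximum of a matrix over a (2r+1)^2 neighbourhood,
# edge-replicated. Separable: rows then columns.
maxFilter <- function(m, r) {
  slide <- function(x, r) {
    out <- x
    n <- nrow(x)
    for (k in seq_len(r)) {
      up <- x[c(seq_len(k) * 0 + 1L, seq_len(n - k)), , drop = FALSE]
      dn <- x[c(seq_len(n - k) + k, rep(n, k)), , drop = FALSE]
      out <- pmax(out, up, dn)
    }
    out
  }
  t(slide(t(slide(m, r)), r))
}

# Bilinear interpolation of matrix `m` (node (r,c) at x=(c-1)*h, y=(r-1)*h)
# at physical points (x, y); clamped at the border.
bilinearAt <- function(m, h, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- pmin(pmax(x / h, 0), nc - 1)
  cy <- pmin(pmax(y / h, 0), nr - 1)
  c0 <- pmin(floor(cx), nc - 2); r0 <- pmin(floor(cy), nr - 2)
  fx <- cx - c0; fy <- cy - r0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# Render 2D Gaussian spots of width sigmaPx (sd, pixels) at sub-pixel centres
# (n x 2 matrix, columns x_px, y_px, 0-based) onto a nrow x ncol canvas.
renderSpots <- function(centersPx, dimPx, sigmaPx, amplitude = 1) {
  img <- matrix(0, dimPx[1], dimPx[2])
  if (!nrow(centersPx)) return(img)
  w <- ceiling(4 * sigmaPx)
  amplitude <- rep_len(amplitude, nrow(centersPx))
  for (i in seq_len(nrow(centersPx))) {
    cx <- centersPx[i, 1]; cy <- centersPx[i, 2]
    cols <- max(1, floor(cx + 1 - w)):min(dimPx[2], ceiling(cx + 1 + w))
    rows <- max(1, floor(cy + 1 - w)):min(dimPx[1], ceiling(cy + 1 + w))
    if (!length(cols) || !length(rows)) next
    gx <- exp(-((cols - 1 - cx)^2) / (2 * sigmaPx^2))
    gy <- exp(-((rows - 1 - cy)^2) / (2 * sigmaPx^2))
    img[rows, cols] <- img[rows, cols] + amplitude[i] * outer(gy, gx)
  }
  img
}

# Filled ellipse mask centred at (cxPx, cyPx) (0-based), semi-axes a, b
# (pixels) with major axis rotated by theta.
ellipseMask <- function(dimPx, cxPx, cyPx, a, b, theta = 0) {
  xs <- matrix(rep(seq_len(dimPx[2]) - 1, each = dimPx[1]), dimPx[1])
  ys <- matrix(rep(seq_len(dimPx[1]) - 1, times = dimPx[2]), dimPx[1])
  dx <- xs - cxPx; dy <- ys - cyPx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Filled disk mask.
diskMask <- function(dimPx, cxPx, cyPx, radiusPx) {
  ellipseMask(dimPx, cxPx, cyPx, radiusPx, radiusPx)
}
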