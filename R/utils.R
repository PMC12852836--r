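## Shared signal/image helpers. All FFT work uses stats::fft / stats::mvfft;
## nothing here depends on the scanner model.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## fold an angle (deg) to the [0, 90] distance-from-normal range
foldIncidence <- function(x) abs(((x + 90) %% 180) - 90)

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal (FFT-based Hilbert transform). For a
#' narrowband pulse this is the usual ultrasound amplitude envelope; the
#' length is preserved and a zero signal maps to a zero envelope.
#'
#' @param x numeric vector, or a matrix whose *columns* are signals.
#' @return nonnegative envelope, same shape as `x`.
#' @export
envelope <- function(x) {
  if (is.matrix(x)) return(Mod(analyticSignal(x)))
  as.vector(Mod(analyticSignal(cbind(x))))
}

## one-sided-spectrum analytic signal; x: matrix with signals in columns
analyticSignal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  stats::mvfft(X, inverse = TRUE) / n
}

## circular fractional delay by `shift` samples (positive = later), applied
## in the frequency domain; exact for bandlimited content away from edges
fourierShift <- function(x, shift) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  ramp <- exp(-2i * pi * k * shift / n)
  if (n %% 2 == 0) ramp[n / 2 + 1] <- Re(ramp[n / 2 + 1])
  Re(stats::mvfft(stats::mvfft(x) * ramp, inverse = TRUE) / n)
}

## shift a vector by a (fractional) number of samples via linear
## interpolation, zero-filled boundaries; positive shift moves content to
## larger indices
linearShift <- function(x, shift) {
  n <- length(x)
  pos <- seq_len(n) - shift
  lo <- floor(pos)
  w <- pos - lo
  get0 <- function(i) ifelse(i >= 1 & i <= n, x[pmax(pmin(i, n), 1)], 0)
  (1 - w) * get0(lo) + w * get0(lo + 1)
}

## bilinear translation of an image by (dy, dx) pixels (positive moves
## content down/right), zero padding outside
translateImage <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  y0 <- floor(ys); wy <- ys - y0
  x0 <- floor(xs); wx <- xs - x0
  pad <- matrix(0, ny + 2, nx + 2)
  ok_y <- y0 >= 0 & y0 <= ny
  ok_x <- x0 >= 0 & x0 <= nx
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  iy <- pmax(pmin(y0 + 1, ny + 1), 1)
  ix <- pmax(pmin(x0 + 1, nx + 1), 1)
  a <- pad[iy, ix, drop = FALSE]
  b <- pad[iy + 1, ix, drop = FALSE]
  c_ <- pad[iy, ix + 1, drop = FALSE]
  d <- pad[iy + 1, ix + 1, drop = FALSE]
  ## bilinear blend, outer-product weights
  Wy <- matrix(wy, ny, nx)
  Wx <- matrix(wx, ny, nx, byrow = TRUE)
  out <- (1 - Wy) * (1 - Wx) * a + Wy * (1 - Wx) * b +
    (1 - Wy) * Wx * c_ + Wy * Wx * d
  out[!ok_y, ] <- 0
  out[, !ok_x] <- 0
  out
}

## FFT-based full cross-correlation of two zero-mean images; returns the
## correlation surface and the lag grids (lag = shift of b relative to a)
crossCorrSurface <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  ny <- nrow(a); nx <- ncol(a)
  stopifnot(nrow(b) == ny, ncol(b) == nx)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / (ny * nx)
  lagY <- c(0:(ny - 1)); lagY[lagY > ny / 2] <- lagY[lagY > ny / 2] - ny
  lagX <- c(0:(nx - 1)); lagX[lagX > nx / 2] <- lagX[lagX > nx / 2] - nx
  list(cc = cc, lagY = lagY, lagX = lagX)
}

## single-point upsampled DFT of the cross-power spectrum around (y0, x0)
## (matrix-multiply implementation of local DFT zoom); F = fa * Conj(fb)
localDftZoom <- function(F, yc, xc, radius, upsample) {
  ny <- nrow(F); nx <- ncol(F)
  n <- ceiling(2 * radius * upsample) + 1
  offs <- (seq_len(n) - 1) / upsample - radius
  ky <- c(0:(ny - 1)); ky[ky > ny / 2] <- ky[ky > ny / 2] - ny
  kx <- c(0:(nx - 1)); kx[kx > nx / 2] <- kx[kx > nx / 2] - nx
  Ey <- exp(2i * pi * outer(yc + offs, ky) / ny)
  Ex <- exp(2i * pi * outer(kx, xc + offs) / nx)
  Re(Ey %*% F %*% Ex)
}

#' Sub-pixel translation between two images
#'
#' Estimates the rigid translation of `b` relative to `a` by FFT
#' cross-correlation: integer peak search (optionally restricted to
#' `maxShift`), then local upsampled-DFT refinement, the standard
#' efficient sub-pixel image-registration scheme. A positive `dy`/`dx`
#' means `b`'s content sits `dy` rows down / `dx` columns right of `a`'s.
#'
#' @param a,b equally sized numeric matrices.
#' @param maxShift optional bound on |shift| in pixels.
#' @param upsample sub-pixel refinement factor (default 50, i.e. 0.02 px
#'   grid).
#' @param method `"ncc"` (cross-correlation of zero-mean images; best
#'   when the images differ by more than a shift) or `"phase"` (phase
#'   correlation; a sharp delta at the true lag, robust to intensity
#'   offsets and cropping).
#' @param hpSigma high-pass prefilter: a Gaussian blur of this sigma
#'   (pixels) is subtracted from both images before correlation, removing
#'   the low-frequency/DC coupling between an image's support and its
#'   content that otherwise skews the sub-pixel peak; 0 disables.
#' @return list with `dy`, `dx` and `peak` (normalized correlation at the
#'   optimum, in `[-1, 1]`).
#' @export
registerTranslation <- function(a, b, maxShift = NULL, upsample = 50,
                                method = c("ncc", "phase"), hpSigma = 8) {
  method <- match.arg(method)
  if (!identical(dim(a), dim(b))) stop("images must have identical shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("insufficient structure: constant image")
  if (hpSigma > 0) {
    a <- a - gaussBlur2(a, hpSigma)
    b <- b - gaussBlur2(b, hpSigma)
  }
  am <- a - mean(a); bm <- b - mean(b)
  ## zero-pad to twice the size: linear (non-circular) correlation, so
  ## large shifts do not alias around the image borders
  ny <- 2 * nrow(a); nx <- 2 * ncol(a)
  pa <- matrix(0, ny, nx); pb <- matrix(0, ny, nx)
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- am
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- bm
  fa <- stats::fft(pa); fb <- stats::fft(pb)
  F <- fa * Conj(fb)
  if (method == "phase") F <- F / pmax(Mod(F), .Machine$double.eps)
  cc <- Re(stats::fft(F, inverse = TRUE)) / (ny * nx)
  lagY <- c(0:(ny - 1)); lagY[lagY > ny / 2] <- lagY[lagY > ny / 2] - ny
  lagX <- c(0:(nx - 1)); lagX[lagX > nx / 2] <- lagX[lagX > nx / 2] - nx
  ok <- matrix(TRUE, ny, nx)
  if (!is.null(maxShift)) {
    ok <- outer(abs(lagY) <= maxShift, abs(lagX) <= maxShift, "&")
    if (!any(ok)) stop("maxShift excludes every lag")
  }
  ccm <- cc; ccm[!ok] <- -Inf
  ij <- arrayInd(which.max(ccm), dim(ccm))
  dy0 <- -lagY[ij[1]]; dx0 <- -lagX[ij[2]]
  ## refine on a +-1.5 px neighborhood at `upsample` resolution
  zoom <- localDftZoom(F, -dy0, -dx0, radius = 1.5, upsample = upsample)
  ij2 <- arrayInd(which.max(zoom), dim(zoom))
  offs <- (seq_len(nrow(zoom)) - 1) / upsample - 1.5
  dy <- dy0 - offs[ij2[1]]
  dx <- dx0 - offs[ij2[2]]
  peak <- if (method == "phase") {
    ## phase-correlation peak: 1 for a pure (uncropped) translation
    max(zoom) / (ny * nx)
  } else {
    max(zoom) / (ny * nx) / (nrow(a) * ncol(a)) /
      sqrt(mean(am^2) * mean(bm^2))
  }
  list(dy = dy, dx = dx, peak = peak)
}

## separable 2-D Gaussian blur of a matrix (edge-clamped kernel)
gaussBlur2 <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(x) {
    n <- nrow(x)
    out <- 0 * x
    for (j in seq_along(k)) {
      src <- pmin(pmax(seq_len(n) + j - r - 1L, 1L), n)
      out <- out + k[j] * x[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

## separable Gaussian blur of a 3-D array along the first two dims (y, x),
## sigma in pixels; reflective padding kept simple via kernel truncation
gaussBlurLateral <- function(vol, sigmaY, sigmaX) {
  blur1 <- function(m, sigma) {
    if (sigma <= 0) return(m)
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    out
  }
  d <- dim(vol)
  m <- matrix(vol, d[1], d[2] * d[3])          # blur along y
  m <- blur1(m, sigmaY)
  vol <- array(m, d)
  vol <- aperm(vol, c(2, 1, 3))                # blur along x
  m <- matrix(vol, d[2], d[1] * d[3])
  m <- blur1(m, sigmaX)
  aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
}

## deterministic child seed derived from a base seed and a stage label,
## kept below 2^31
childSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
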