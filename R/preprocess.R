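#' Homomorphic brightness normalization of a projection stack
#'
#' Removes multiplicative low-frequency illumination bias from bright-field
#' projections. Each projection is log-transformed, filtered in the 2D
#' frequency domain with the Gaussian high-emphasis transfer function
#' `H(f) = lowGain + (highGain - lowGain) * (1 - exp(-f^2 / (2 cutoff^2)))`
#' (f = radial frequency in cycles/pixel), and exponentiated. Low
#' frequencies (illumination bias) are attenuated by `lowGain`, high
#' frequencies (cell-scale content) pass at `highGain`. The same filter is
#' applied to every projection in the stack.
#'
#' Intensities must be positive; if zeros are present a small epsilon
#' (1e-6 of the stack maximum) is added and a message is emitted.
#'
#' @param stack a [ProjectionStack-class] (transmission-domain intensities).
#' @param cutoffFreq transition frequency in cycles/pixel, in (0, 0.5).
#'   Default 0.02.
#' @param lowGain low-frequency gain, in (0, 1]. Default 0.3.
#' @param highGain high-frequency gain, >= 1. Default 1.
#' @return the filtered [ProjectionStack-class], strictly positive.
#' @export
homomorphicFilter <- function(stack, cutoffFreq = 0.02, lowGain = 0.3,
                              highGain = 1) {
  stopifnot(is(stack, "ProjectionStack"))
  if (!(lowGain > 0 && lowGain <= 1)) stop("lowGain must lie in (0, 1]")
  if (highGain < 1) stop("highGain must be >= 1")
  if (!(cutoffFreq > 0 && cutoffFreq < 0.5)) stop("cutoffFreq must lie in (0, 0.5)")
  d <- stack@data
  if (any(d <= 0)) {
    eps <- 1e-6 * max(d)
    if (eps <= 0) eps <- 1e-6
    d <- d + eps
    message(sprintf("homomorphicFilter: added epsilon %.3g to non-positive intensities", eps))
  }
  H <- homomorphicTransfer(dim(d)[2L], dim(d)[3L], cutoffFreq, lowGain, highGain)
  n <- prod(dim(d)[2:3])
  for (a in seq_len(dim(d)[1L])) {
    lg <- log(d[a, , ])
    flt <- Re(fft(fft(lg) * H, inverse = TRUE)) / n
    d[a, , ] <- exp(flt)
  }
  initialize(stack, data = d)
}

# Gaussian high-emphasis transfer function on the 2D DFT grid.
homomorphicTransfer <- function(nrow, ncol, cutoff, lowGain, highGain) {
  fy <- fftFreq(nrow)
  fx <- fftFreq(ncol)
  f2 <- outer(fy^2, fx^2, `+`)
  lowGain + (highGain - lowGain) * (1 - exp(-f2 / (2 * cutoff^2)))
}

# DFT sample frequencies in cycles/sample (numpy fftfreq layout).
fftFreq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  k / n
}

#' 2D median filter applied to every projection
#'
#' Removes isolated hot pixels (random photon noise) from fluorescence
#' projections. `window = 1` is the identity.
#'
#' @param stack a [ProjectionStack-class].
#' @param window odd window edge length (>= 1). Default 3.
#' @return the filtered [ProjectionStack-class].
#' @export
medianFilterStack <- function(stack, window = 3L) {
  stopifnot(is(stack, "ProjectionStack"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1) return(stack)
  d <- stack@data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  r <- (window - 1L) %/% 2L
  for (a in seq_len(dim(d)[1L])) {
    # EBImage's constant-time median filter operates on [0, 1] images
    frame <- (d[a, , ] - lo) / scale
    d[a, , ] <- EBImage::medianFilter(frame, r) * scale + lo
  }
  initialize(stack, data = d)
}

#' Percentile-based linear brightness adjustment
#'
#' Linearly rescales the stack's `[low, high]` percentile intensity range
#' onto `outRange` (a monotone map; values beyond the percentiles are
#' clipped to the output range). Errors on a constant stack, for which the
#' rescale is undefined.
#'
#' @param stack a [ProjectionStack-class].
#' @param outRange target `c(low, high)` intensities. Default `c(0, 1)`.
#' @param percentiles source percentiles in percent. Default `c(0.5, 99.5)`.
#' @return the rescaled [ProjectionStack-class].
#' @export
brightnessAdjust <- function(stack, outRange = c(0, 1),
                             percentiles = c(0.5, 99.5)) {
  stopifnot(is(stack, "ProjectionStack"), length(outRange) == 2L,
            outRange[2L] > outRange[1L], outRange[1L] >= 0)
  d <- stack@data
  q <- quantile(d, percentiles / 100, names = FALSE)
  if (q[2L] <= q[1L]) {
    if (max(d) == min(d)) stop("brightnessAdjust: constant stack has no dynamic range")
    q <- range(d)
  }
  out <- (d - q[1L]) / (q[2L] - q[1L]) * (outRange[2L] - outRange[1L]) + outRange[1L]
  out <- pmin(pmax(out, outRange[1L]), outRange[2L])
  initialize(stack, data = out)
}

#' Align and compose live/dead fluorescence channels
#'
#' For every angle, finds the integer rigid translation of the dead-channel
#' projection that maximizes its cross-correlation with the live-channel
#' projection (FFT cross-correlation of mean-subtracted frames, peak
#' searched within `searchRadiusPx`), applies it, and stacks the channels.
#' An all-zero dead frame gets zero shift with a warning.
#'
#' @param live live-channel [ProjectionStack-class].
#' @param dead dead-channel [ProjectionStack-class]; must share the angle
#'   list and frame shape.
#' @param searchRadiusPx maximum shift searched per axis. Default 10.
#' @return list with `composite` (array `angle x row x col x channel`,
#'   channels live/dead), `shifts` (data.frame angle, dy, dx), and the two
#'   aligned stacks `live`, `dead`.
#' @export
composeLiveDead <- function(live, dead, searchRadiusPx = 10L) {
  stopifnot(is(live, "ProjectionStack"), is(dead, "ProjectionStack"))
  if (!isTRUE(all.equal(live@anglesDeg, dead@anglesDeg))) {
    stop("live and dead stacks must share the same angle list")
  }
  if (!identical(dim(live@data), dim(dead@data))) {
    stop("live and dead stacks must share the same frame shape")
  }
  nA <- dim(live@data)[1L]
  shifts <- data.frame(angle = live@anglesDeg, dy = integer(nA), dx = integer(nA))
  aligned <- dead@data
  warned <- FALSE
  for (a in seq_len(nA)) {
    df <- dead@data[a, , ]
    if (all(df == 0)) {
      if (!warned) {
        warning("composeLiveDead: all-zero dead frame(s); zero shift applied")
        warned <- TRUE
      }
      next
    }
    sh <- bestShift(live@data[a, , ], df, searchRadiusPx)
    shifts$dy[a] <- sh[1L]
    shifts$dx[a] <- sh[2L]
    aligned[a, , ] <- shiftFrame(df, sh[1L], sh[2L])
  }
  comp <- array(0, dim = c(dim(live@data), 2L),
                dimnames = list(NULL, NULL, NULL, c("live", "dead")))
  comp[, , , 1L] <- live@data
  comp[, , , 2L] <- aligned
  list(composite = comp, shifts = shifts, live = live,
       dead = initialize(dead, data = aligned))
}

# Integer (dy, dx) maximizing cross-correlation of b shifted onto a.
bestShift <- function(a, b, radius) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE)) / length(a0)
  n1 <- nrow(a); n2 <- ncol(a)
  lag1 <- fftLags(n1); lag2 <- fftLags(n2)
  keep1 <- abs(lag1) <= radius
  keep2 <- abs(lag2) <= radius
  sub <- cc[keep1, keep2, drop = FALSE]
  idx <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  c(lag1[keep1][idx[1L]], lag2[keep2][idx[2L]])
}

fftLags <- function(n) {
  l <- seq_len(n) - 1L
  l[l > n / 2] <- l[l > n / 2] - n
  l
}

# Shift a matrix by integer (dy, dx), zero-filling exposed edges.
shiftFrame <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  src1 <- seq_len(nrow(m)) - dy
  src2 <- seq_len(ncol(m)) - dx
  ok1 <- src1 >= 1L & src1 <= nrow(m)
  ok2 <- src2 >= 1L & src2 <= ncol(m)
  out[which(ok1), which(ok2)] <- m[src1[ok1], src2[ok2], drop = FALSE]
  out
}
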