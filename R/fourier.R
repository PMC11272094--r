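# FFT plumbing shared by the forward simulator and the retrieval filters.
#
# All filtered transforms mirror-pad the raster to twice its size first and
# crop afterwards. The mirror extension is even-symmetric, and every Fourier
# multiplier used here is even in frequency, so filtering preserves the
# symmetry class: pad -> filter -> crop operations compose exactly (a forward
# multiplier followed by its inverse is the identity to machine precision),
# while wraparound artefacts from the periodic FFT are pushed outside the
# cropped frame.

# DFT frequencies in cycles per unit length for n samples with spacing d
fft_freq <- function(n, d) {
  f <- 0:(n - 1)
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f / (n * d)
}

# |nu|^2 grid (cycles^2 / mm^2) for an nr x nc raster
freq_sq_grid <- function(nr, nc, pixel_mm) {
  fy <- fft_freq(nr, pixel_mm)
  fx <- fft_freq(nc, pixel_mm)
  outer(fy^2, fx^2, `+`)
}

# mirror-pad a matrix to (2 nr) x (2 nc)
mirror_pad <- function(x) {
  x2 <- rbind(x, x[nrow(x):1, , drop = FALSE])
  cbind(x2, x2[, ncol(x2):1, drop = FALSE])
}

crop_pad <- function(x, nr, nc) x[seq_len(nr), seq_len(nc), drop = FALSE]

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# core work-horse: y = Re(ifft(fft(pad(x)) * m)) cropped, for a multiplier
# matrix m built on the padded grid. Accepts a precomputed padded spectrum to
# amortise the forward FFT across multipliers.
filtered_transform <- function(x = NULL, m, spectrum_pad = NULL,
                               nr = NULL, nc = NULL) {
  if (is.null(spectrum_pad)) {
    nr <- nrow(x); nc <- ncol(x)
    spectrum_pad <- fft2(mirror_pad(x))
  }
  crop_pad(Re(ifft2(spectrum_pad * m)), nr, nc)
}

# Gaussian blur of an image via Fourier multiplier exp(-2 pi^2 sigma^2 nu^2)
gaussian_blur <- function(x, sigma_mm, pixel_mm) {
  if (sigma_mm <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  nu2 <- freq_sq_grid(2 * nr, 2 * nc, pixel_mm)
  filtered_transform(x, exp(-2 * pi^2 * sigma_mm^2 * nu2))
}
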