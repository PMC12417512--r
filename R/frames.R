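# Rasterization of the 8x8 electrode array onto a refined pixel grid,
# producing the image sequence consumed by the optical-flow solver.
#
# Pixel lattice (G = interp_grid):
#   pixel i (1..G) on the spline axis sits at s = (i-1) * 8 / G  (periodic)
#   pixel j (1..G) on the electrode axis at  e = (j-1) * 7 / (G-1) (clamped)

pixel_coords <- function(G) {
  list(s = (seq_len(G) - 1) * 8 / G,
       e = (seq_len(G) - 1) * 7 / (G - 1))
}

# grid-units per pixel step along each axis
pixel_scale <- function(G) c(s = 8 / G, e = 7 / (G - 1))

# Sparse G^2 x 64 bilinear interpolation matrix from electrode nodes to
# pixels; periodic in the spline axis, clamped on the electrode axis.
# Pixel (i, j) maps to row i + (j-1) * G (spline axis fastest, i.e.
# column-major for a G x G matrix with rows = spline).
electrode_interp_matrix <- function(G) {
  pc <- pixel_coords(G)
  px <- expand.grid(s = pc$s, e = pc$e)
  .bilinear_weights_electrodes(px$s, px$e)
}

# Bilinear weights of arbitrary (s, e) points w.r.t. the 64 electrode
# nodes (canonical order); returns a sparse n x 64 matrix.
.bilinear_weights_electrodes <- function(s, e) {
  n <- length(s)
  s <- s %% 8
  e <- pmin(pmax(e, 0), 7)
  s0 <- floor(s); fs <- s - s0
  e0 <- pmin(floor(e), 6); fe <- e - e0
  s1 <- (s0 + 1) %% 8
  idx <- function(si, ei) si * 8 + ei + 1  # canonical order: spline-major
  i <- rep(seq_len(n), 4)
  j <- c(idx(s0, e0), idx(s1, e0), idx(s0, e0 + 1), idx(s1, e0 + 1))
  w <- c((1 - fs) * (1 - fe), fs * (1 - fe), (1 - fs) * fe, fs * fe)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, 64))
}

# Bilinear weights of arbitrary (s, e) points w.r.t. the G^2 pixel lattice
# (periodic spline axis, clamped electrode axis); sparse n x G^2.
.bilinear_weights_pixels <- function(s, e, G) {
  n <- length(s)
  sc <- pixel_scale(G)
  x <- (s %% 8) / sc["s"]                       # pixel units, periodic in [0, G)
  y <- pmin(pmax(e, 0), 7) / sc["e"]            # pixel units in [0, G-1]
  x0 <- floor(x); fx <- x - x0
  y0 <- pmin(floor(y), G - 2); fy <- y - y0
  x1 <- (x0 + 1) %% G
  idx <- function(xi, yi) xi + yi * G + 1
  i <- rep(seq_len(n), 4)
  j <- c(idx(x0, y0), idx(x1, y0), idx(x0, y0 + 1), idx(x1, y0 + 1))
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, G * G))
}

# Separable Gaussian blur operator on the pixel lattice as a sparse
# G^2 x G^2 matrix (periodic spline axis, renormalized clamp on the
# electrode axis). sigma in pixels; sigma <= 0 gives identity.
.blur_matrix <- function(G, sigma) {
  if (sigma <= 0) return(Matrix::Diagonal(G * G))
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # 1-D operators
  Bp <- matrix(0, G, G)  # periodic
  Bc <- matrix(0, G, G)  # clamped
  for (i in seq_len(G)) {
    for (d in -h:h) {
      Bp[i, ((i - 1 + d) %% G) + 1] <- Bp[i, ((i - 1 + d) %% G) + 1] + k[d + h + 1]
      jc <- min(max(i + d, 1), G)
      Bc[i, jc] <- Bc[i, jc] + k[d + h + 1]
    }
  }
  Matrix::kronecker(Matrix::Matrix(Bc, sparse = TRUE),
                    Matrix::Matrix(Bp, sparse = TRUE))
}

#' Build the interpolated image sequence from a preprocessed recording
#'
#' Channels are temporally smoothed (Gaussian, `presmooth_sigma_ms`),
#' resampled to `frame_rate_hz`, infilled at quality-inadmissible
#' electrodes by inverse-distance weighting from admissible neighbours
#' within 2 grid units, bilinearly interpolated onto the
#' `interp_grid` x `interp_grid` pixel lattice (periodic in the spline
#' axis) and spatially smoothed (`presmooth_sigma_px`).
#'
#' @param rec A preprocessed, normalized `basket_recording`.
#' @param quality Optional [assess_quality()] mask used for infill.
#' @param hp Hyperparameters.
#' @return An object of class `frame_sequence`: `frames` (G^2 x n_frames
#'   matrix, one column per frame, spline axis fastest), `grid` (G),
#'   `frame_rate_hz`, `duration_s`.
#' @export
build_frames <- function(rec, quality = NULL, hp = egf_params()) {
  stopifnot(inherits(rec, "basket_recording"))
  fs <- rec$sample_rate
  if (hp$frame_rate_hz > fs) stop("bad frame rate: exceeds sample rate")
  G <- as.integer(hp$interp_grid)
  n <- ncol(rec$signals)
  x <- rec$signals

  # temporal Gaussian smoothing
  sig_samp <- hp$presmooth_sigma_ms / 1000 * fs
  if (sig_samp > 0.25) {
    h <- max(1L, ceiling(3 * sig_samp))
    k <- exp(-(seq(-h, h))^2 / (2 * sig_samp^2)); k <- k / sum(k)
    pad <- cbind(x[, rep(1L, h), drop = FALSE], x, x[, rep(n, h), drop = FALSE])
    x <- t(apply(pad, 1, function(ch) stats::filter(ch, k, sides = 2)))
    x <- x[, (h + 1):(h + n), drop = FALSE]
  }

  # temporal resampling to the frame grid (linear interpolation)
  nf <- floor(rec$duration_s * hp$frame_rate_hz + 1e-9)
  ft <- (seq_len(nf) - 1) / hp$frame_rate_hz
  pos <- ft * fs + 1
  i0 <- pmin(pmax(floor(pos), 1), n - 1)
  fr <- pos - i0
  E <- x[, i0, drop = FALSE] * rep(1 - fr, each = N_CHANNELS) +
    x[, i0 + 1, drop = FALSE] * rep(fr, each = N_CHANNELS)

  # infill inadmissible electrodes from admissible neighbours (IDW, r <= 2)
  if (!is.null(quality)) {
    epos <- electrode_grid_positions()
    dmat <- outer(seq_len(N_CHANNELS), seq_len(N_CHANNELS),
                  function(a, b) grid_distance(epos[a, , drop = FALSE],
                                               epos[b, , drop = FALSE]))
    segs <- segment_index_at(ft, rec$duration_s, hp)
    for (k in unique(segs)) {
      adm <- quality$admissible[, k]
      bad <- which(!adm)
      if (!length(bad) || all(!adm)) next
      cols <- which(segs == k)
      for (b in bad) {
        nb <- which(adm & dmat[b, ] <= 2 & dmat[b, ] > 0)
        if (!length(nb)) nb <- which(adm)
        w <- 1 / pmax(dmat[b, nb], 0.5)
        E[b, cols] <- colSums(E[nb, cols, drop = FALSE] * w) / sum(w)
      }
    }
  }

  P <- electrode_interp_matrix(G)
  Fm <- as.matrix(P %*% E)
  if (hp$presmooth_sigma_px > 0) {
    Fm <- as.matrix(.blur_matrix(G, hp$presmooth_sigma_px) %*% Fm)
  }
  structure(list(frames = Fm, grid = G, frame_rate_hz = hp$frame_rate_hz,
                 duration_s = rec$duration_s),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d @ %g Hz\n",
              ncol(x$frames), x$grid, x$grid, x$frame_rate_hz))
  invisible(x)
}
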