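# Independent reference implementations used as oracles. These are
# deliberately slow and dense (explicit loops), sharing no code with the
# package internals.

# Reference Horn-Schunck: same mathematical scheme as the solver (joint
# pair standardization; central spatial differences of the pair average,
# periodic rows / replicate-clamped columns; two-frame temporal
# difference; Jacobi updates with the 4-neighbour average), written as
# plain nested loops.
reference_horn_schunck <- function(a, b, alpha, n_iter) {
  G <- nrow(a)
  wrap <- function(i) ((i - 1) %% G) + 1
  clmp <- function(i) min(max(i, 1), G)
  mu <- mean(c(a, b))
  sdv <- sqrt(mean((c(a, b) - mu)^2))
  u <- matrix(0, G, G); v <- matrix(0, G, G)
  if (sdv < 1e-12) return(list(u = u, v = v))
  a <- (a - mu) / sdv; b <- (b - mu) / sdv
  A <- (a + b) / 2
  Ix <- matrix(0, G, G); Iy <- matrix(0, G, G)
  for (i in 1:G) for (j in 1:G) {
    Ix[i, j] <- (A[wrap(i + 1), j] - A[wrap(i - 1), j]) / 2
    Iy[i, j] <- (A[i, clmp(j + 1)] - A[i, clmp(j - 1)]) / 2
  }
  It <- b - a
  for (it in seq_len(n_iter)) {
    un <- u; vn <- v
    for (i in 1:G) for (j in 1:G) {
      ub <- (u[wrap(i - 1), j] + u[wrap(i + 1), j] +
               u[i, clmp(j - 1)] + u[i, clmp(j + 1)]) / 4
      vb <- (v[wrap(i - 1), j] + v[wrap(i + 1), j] +
               v[i, clmp(j - 1)] + v[i, clmp(j + 1)]) / 4
      num <- Ix[i, j] * ub + Iy[i, j] * vb + It[i, j]
      den <- alpha^2 + Ix[i, j]^2 + Iy[i, j]^2
      un[i, j] <- ub - Ix[i, j] * num / den
      vn[i, j] <- vb - Iy[i, j] * num / den
    }
    u <- un; v <- vn
  }
  list(u = u, v = v)
}

# Periodic bilinear interpolation oracle: value of the 8x8 electrode
# array (canonical order vector) at one (s, e) point.
reference_bilinear <- function(vals64, s, e) {
  s <- s %% 8; e <- min(max(e, 0), 7)
  s0 <- floor(s); fs <- s - s0
  e0 <- min(floor(e), 6); fe <- e - e0
  g <- function(si, ei) vals64[(si %% 8) * 8 + ei + 1]
  (1 - fs) * (1 - fe) * g(s0, e0) + fs * (1 - fe) * g(s0 + 1, e0) +
    (1 - fs) * fe * g(s0, e0 + 1) + fs * fe * g(s0 + 1, e0 + 1)
}

# Exhaustive ring radial-index maximizer: brute-force scan of all pixel
# centres by direct ring sampling (no shared code with the package scan).
reference_ring_argmax <- function(u, v, radius = 2, m = 16) {
  G <- nrow(u)
  scs <- 8 / G; sce <- 7 / (G - 1)
  sample_field <- function(f, s, e) {
    reference_bilinear_pixels(f, s / scs, e / sce, G)
  }
  best <- c(-Inf, NA, NA)
  phi <- 2 * pi * (0:(m - 1)) / m
  for (i in 1:G) for (j in 1:G) {
    s <- (i - 1) * scs; e <- (j - 1) * sce
    acc <- 0
    for (k in seq_len(m)) {
      ss <- s + radius * cos(phi[k]); ee <- e + radius * sin(phi[k])
      us <- sample_field(u, ss %% 8, min(max(ee, 0), 7)) * scs
      vs <- sample_field(v, ss %% 8, min(max(ee, 0), 7)) * sce
      nr <- sqrt(us^2 + vs^2)
      if (nr > 1e-9) acc <- acc + (us * cos(phi[k]) + vs * sin(phi[k])) / nr
    }
    val <- acc / m
    if (val > best[1]) best <- c(val, s, e)
  }
  list(radial = best[1], s = best[2], e = best[3])
}

# bilinear on the pixel lattice (x, y in pixel units, x periodic)
reference_bilinear_pixels <- function(f, x, y, G) {
  x0 <- floor(x); fx <- x - x0
  y0 <- min(max(floor(y), 0), G - 2); fy <- y - y0
  g <- function(xi, yi) f[(xi %% G) + 1, min(max(yi, 0), G - 1) + 1]
  (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x0 + 1, y0) +
    (1 - fx) * fy * g(x0, y0 + 1) + fx * fy * g(x0 + 1, y0 + 1)
}

# Hand product-limit estimator (no censoring handling needed beyond
# standard right censoring), used as the KM oracle.
reference_product_limit <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  S <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    S <- S * (1 - d / n_risk)
    out$surv[k] <- S
  }
  out
}

# Ideal synthetic flow fields (pixel units), for scan tests.  The fields
# are defined in grid units and converted so that the grid-unit flow is
# exactly radial / rotational about the centre.
ideal_field <- function(G, centre, kind = c("radial", "vortex"),
                        drift = c(0, 0)) {
  kind <- match.arg(kind)
  scs <- 8 / G; sce <- 7 / (G - 1)
  s <- (seq_len(G) - 1) * scs; e <- (seq_len(G) - 1) * sce
  u <- matrix(0, G, G); v <- matrix(0, G, G)
  for (i in 1:G) for (j in 1:G) {
    ds <- ((s[i] - centre[1] + 4) %% 8) - 4
    de <- e[j] - centre[2]
    r <- sqrt(ds^2 + de^2)
    if (r < 1e-9) r <- 1
    gu <- if (kind == "radial") ds / r else -de / r
    gv <- if (kind == "radial") de / r else ds / r
    u[i, j] <- (gu + drift[1]) / scs
    v[i, j] <- (gv + drift[2]) / sce
  }
  list(u = u, v = v)
}
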