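# Flow-singularity detection.  A candidate source is scored by ring
# indices: flow vectors sampled on a ring of `singularity_radius` grid
# units around a point are unit-normalized and projected on the outward
# radial and tangential unit vectors.  The mean projections (radial index,
# tangential index) are dimensionless, bounded in [-1, 1]; an ideal
# divergent source scores radial index 1, an ideal rotor |tangential| 1.

.ring_cache <- new.env(parent = emptyenv())

# Precomputed sparse samplers: for each of m ring angles, a G^2 x G^2
# matrix taking a field to its value sampled at (pixel + ring offset).
ring_samplers <- function(G, radius, m) {
  key <- paste(G, radius, m, sep = "_")
  if (!is.null(.ring_cache[[key]])) return(.ring_cache[[key]])
  pc <- pixel_coords(G)
  px <- expand.grid(s = pc$s, e = pc$e)
  phi <- 2 * pi * (seq_len(m) - 1) / m
  S <- lapply(seq_len(m), function(k) {
    .bilinear_weights_pixels(px$s + radius * cos(phi[k]),
                             px$e + radius * sin(phi[k]), G)
  })
  out <- list(phi = phi, S = S)
  .ring_cache[[key]] <- out
  out
}

# Convert pixel/frame flow to grid-units/frame (the two axes have
# different pixel spacings).
.flow_to_grid_units <- function(u, v, G) {
  sc <- pixel_scale(G)
  list(u = u * sc[["s"]], v = v * sc[["e"]])
}

#' Ring radial/tangential index fields of a flow field
#'
#' @param u,v G x G flow components (pixels/frame).
#' @param hp Hyperparameters (`singularity_radius`, `ring_samples`).
#' @return List of G x G matrices `radial` and `tangential`.
#' @export
ring_index_fields <- function(u, v, hp = egf_params()) {
  G <- nrow(u)
  rs <- ring_samplers(G, hp$singularity_radius, as.integer(hp$ring_samples))
  g <- .flow_to_grid_units(as.vector(u), as.vector(v), G)
  R <- numeric(G * G); Tg <- numeric(G * G)
  for (k in seq_along(rs$phi)) {
    us <- as.numeric(rs$S[[k]] %*% g$u)
    vs <- as.numeric(rs$S[[k]] %*% g$v)
    nrm <- sqrt(us^2 + vs^2)
    ok <- nrm > 1e-9
    us <- ifelse(ok, us / nrm, 0)
    vs <- ifelse(ok, vs / nrm, 0)
    cr <- cos(rs$phi[k]); sr <- sin(rs$phi[k])
    R <- R + us * cr + vs * sr
    Tg <- Tg + (-us * sr + vs * cr)
  }
  m <- length(rs$phi)
  list(radial = matrix(R / m, G, G), tangential = matrix(Tg / m, G, G))
}

# Ring indices of one flow field evaluated at arbitrary grid positions.
ring_index_at <- function(u, v, pos, hp) {
  G <- nrow(u)
  pos <- rbind(pos)
  m <- as.integer(hp$ring_samples)
  phi <- 2 * pi * (seq_len(m) - 1) / m
  g <- .flow_to_grid_units(as.vector(u), as.vector(v), G)
  out <- matrix(0, nrow(pos), 2, dimnames = list(NULL, c("radial", "tangential")))
  for (p in seq_len(nrow(pos))) {
    W <- .bilinear_weights_pixels(pos[p, 1] + hp$singularity_radius * cos(phi),
                                  pos[p, 2] + hp$singularity_radius * sin(phi), G)
    us <- as.numeric(W %*% g$u); vs <- as.numeric(W %*% g$v)
    nrm <- sqrt(us^2 + vs^2); ok <- nrm > 1e-9
    us <- ifelse(ok, us / nrm, 0); vs <- ifelse(ok, vs / nrm, 0)
    out[p, 1] <- mean(us * cos(phi) + vs * sin(phi))
    out[p, 2] <- mean(-us * sin(phi) + vs * cos(phi))
  }
  out
}

# 8-neighbour local maxima of a G x G field (periodic rows, clamped cols).
.local_maxima <- function(f) {
  G <- nrow(f)
  up <- f[c(G, 1:(G - 1)), , drop = FALSE]
  dn <- f[c(2:G, 1), , drop = FALSE]
  lf <- f[, c(1, 1:(G - 1)), drop = FALSE]
  rt <- f[, c(2:G, G), drop = FALSE]
  ul <- up[, c(1, 1:(G - 1)), drop = FALSE]; ur <- up[, c(2:G, G), drop = FALSE]
  dl <- dn[, c(1, 1:(G - 1)), drop = FALSE]; dr <- dn[, c(2:G, G), drop = FALSE]
  f >= up & f >= dn & f >= lf & f >= rt & f >= ul & f >= ur & f >= dl & f >= dr
}

#' Scan a segment's mean flow for singularities
#'
#' Candidates are local maxima of the ring radial-index field with radial
#' index at least `radial_index_min` (divergent candidates) or local
#' maxima of the absolute tangential-index field at or above
#' `curl_rotational` (rotational candidates). Non-maximum suppression
#' keeps candidates at least `cluster_radius` apart (periodic metric);
#' output is sorted by radial index descending, ties broken by tangential
#' index then lexicographic position, making the scan fully deterministic.
#'
#' @param seg A `segment_flow` (or any list with `u`, `v`,
#'   `segment_index`).
#' @param hp Hyperparameters.
#' @return A data.frame with columns `s`, `e`, `radial_index`,
#'   `tangential_index`, `segment_index` (possibly 0 rows).
#' @export
singularity_scan <- function(seg, hp = egf_params()) {
  if (!all(is.finite(seg$u)) || !all(is.finite(seg$v))) {
    stop("corrupt data: non-finite flow field")
  }
  G <- nrow(seg$u)
  f <- ring_index_fields(seg$u, seg$v, hp)
  pc <- pixel_coords(G)
  cand_r <- which(.local_maxima(f$radial) & f$radial >= hp$radial_index_min)
  cand_t <- which(.local_maxima(abs(f$tangential)) &
                    abs(f$tangential) >= hp$curl_rotational)
  cand <- union(cand_r, cand_t)
  if (!length(cand)) {
    return(data.frame(s = numeric(0), e = numeric(0),
                      radial_index = numeric(0), tangential_index = numeric(0),
                      segment_index = integer(0)))
  }
  ij <- arrayInd(cand, c(G, G))
  df <- data.frame(s = pc$s[ij[, 1]], e = pc$e[ij[, 2]],
                   radial_index = f$radial[cand],
                   tangential_index = f$tangential[cand],
                   segment_index = seg$segment_index %||% NA_integer_)
  df <- df[order(-df$radial_index, -abs(df$tangential_index), df$s, df$e), ,
           drop = FALSE]
  # non-maximum suppression within cluster_radius
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- grid_distance(as.matrix(df[keep, c("s", "e")]),
                       matrix(unlist(df[i, c("s", "e")]), sum(keep), 2,
                              byrow = TRUE))
    keep[i] <- all(d > hp$cluster_radius)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
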