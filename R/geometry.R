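# Basket geometry: 8 splines (A..H) x 8 electrodes (1..8).
#
# Grid convention used throughout the package:
#   * axis 1 ("spline"): continuous coordinate in [0, 8), periodic
#     (the basket is circumferentially closed); A = 0 ... H = 7.
#   * axis 2 ("electrode"): continuous coordinate in [0, 7], clamped
#     (distal/proximal ends are open); electrode 1 -> 0 ... 8 -> 7.
#   Electrode 1 is taken as the distal row; the clinical labelling
#   orientation is not standardized, so this is a documented convention.

SPLINE_LETTERS <- LETTERS[1:8]
N_CHANNELS <- 64L
N_SPLINES <- 8L
N_PER_SPLINE <- 8L

#' Canonical basket channel labels
#'
#' The 64 labels "A1".."H8" in canonical order (spline-major: A1, A2, ...,
#' A8, B1, ..., H8). All recording matrices in the package use this row
#' order.
#'
#' @return Character vector of length 64.
#' @export
basket_channel_labels <- function() {
  as.vector(vapply(SPLINE_LETTERS,
                   function(l) paste0(l, 1:8),
                   character(N_PER_SPLINE)))
}

#' Grid coordinates of the 64 electrodes
#'
#' @return A 64 x 2 matrix with columns `s` (spline axis, 0..7) and `e`
#'   (electrode axis, 0..7), rows in canonical label order.
#' @export
electrode_grid_positions <- function() {
  s <- rep(0:7, each = 8)
  e <- rep(0:7, times = 8)
  m <- cbind(s = as.numeric(s), e = as.numeric(e))
  rownames(m) <- basket_channel_labels()
  m
}

#' Convert a channel or region label to a grid position
#'
#' Single letter + digit ("D4") names an electrode node. Two adjacent
#' letters and/or two adjacent digits ("DE45", "G23", "HA2") name the
#' midpoint between the coordinates; letter adjacency wraps around the
#' basket (H and A are neighbours), electrode digits do not.
#'
#' @param label Character scalar, e.g. "A1", "DE45", "HA2".
#' @return Named numeric vector `c(s = , e = )`.
#' @examples
#' label_to_grid("A1")    # c(0, 0)
#' label_to_grid("DE45")  # c(3.5, 3.5)
#' @export
label_to_grid <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!grepl("^[A-H]{1,2}[1-8]{1,2}$", label)) {
    stop("bad label: ", label)
  }
  letters_part <- strsplit(gsub("[0-9]", "", label), "")[[1]]
  digits_part <- as.integer(strsplit(gsub("[A-H]", "", label), "")[[1]])
  li <- match(letters_part, SPLINE_LETTERS) - 1L
  if (length(li) == 2L) {
    step <- (li[2] - li[1]) %% 8L
    if (step != 1L && step != 7L) stop("bad label: non-adjacent splines in ", label)
    # periodic midpoint of the two adjacent splines
    s <- (li[1] + (if (step == 1L) 0.5 else -0.5)) %% 8
  } else {
    s <- as.numeric(li)
  }
  if (length(digits_part) == 2L) {
    if (abs(digits_part[2] - digits_part[1]) != 1L) {
      stop("bad label: non-adjacent electrodes in ", label)
    }
    e <- mean(digits_part) - 1
  } else {
    e <- as.numeric(digits_part - 1L)
  }
  c(s = s, e = e)
}

#' Convert an integer grid node to its channel label
#'
#' Inverse of [label_to_grid()] on the 64 electrode nodes.
#'
#' @param pos Numeric vector `c(s, e)` with integer entries in 0..7.
#' @return Character scalar label.
#' @export
grid_to_label <- function(pos) {
  s <- pos[[1]] %% 8
  e <- pos[[2]]
  if (s != round(s) || e != round(e) || e < 0 || e > 7) {
    stop("bad label: not an electrode node")
  }
  paste0(SPLINE_LETTERS[as.integer(round(s)) + 1L], as.integer(round(e)) + 1L)
}

#' Distance on the basket grid (periodic in the spline axis)
#'
#' @param a,b Positions: numeric `c(s, e)`, or matrices with columns s, e.
#' @return Numeric distance(s) in grid units.
#' @export
grid_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ds <- abs(a[, 1] - b[, 1]) %% 8
  ds <- pmin(ds, 8 - ds)
  de <- a[, 2] - b[, 2]
  sqrt(ds^2 + de^2)
}

# Signed periodic displacement on the spline axis, in (-4, 4].
spline_displacement <- function(from, to) {
  d <- (to - from) %% 8
  ifelse(d > 4, d - 8, d)
}

# Circular mean of spline coordinates (period 8); plain mean on the
# electrode axis.
grid_centroid <- function(pos) {
  pos <- rbind(pos)
  ang <- pos[, 1] * 2 * pi / 8
  s <- (atan2(mean(sin(ang)), mean(cos(ang))) * 8 / (2 * pi)) %% 8
  c(s = s, e = mean(pos[, 2]))
}
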