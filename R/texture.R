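# Local binary pattern (LBP) and gradient-weighted LBP (GLBP) texture maps,
# and assembly of the 5-channel input tensor consumed by the segmenter.
#
# Coordinate conventions: images are matrices indexed [row, col] with origin
# top-left; x = column, y = row. Neighbour i of P sits at angle 2*pi*i/P at
# radius R, with the y offset measured downwards.

# reflect padding (edge pixel not duplicated), then shift by (dr, dc)
shift_reflect <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 2 - (seq_len(h) + dr)), 2 * h - (seq_len(h) + dr))
  ci <- pmin(pmax(seq_len(w) + dc, 2 - (seq_len(w) + dc)), 2 * w - (seq_len(w) + dc))
  m[ri, ci, drop = FALSE]
}

# value of m at fractional offset (dr, dc) from every pixel, bilinear
shift_bilinear <- function(m, dr, dc) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  (1 - fr) * (1 - fc) * shift_reflect(m, r0, c0) +
  (1 - fr) * fc       * shift_reflect(m, r0, c0 + 1) +
  fr       * (1 - fc) * shift_reflect(m, r0 + 1, c0) +
  fr       * fc       * shift_reflect(m, r0 + 1, c0 + 1)
}

neighbour_offsets <- function(P, R) {
  i <- seq_len(P)
  list(dx = R * cos(2 * pi * i / P), dy = R * sin(2 * pi * i / P))
}

neighbour_value <- function(m, dy, dx, interp) {
  if (interp == "nearest") shift_reflect(m, round(dy), round(dx))
  else shift_bilinear(m, dy, dx)
}

#' Convert an RGB image to grayscale
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, returned as a float matrix on
#' the 0-255 scale.
#'
#' @param image `H x W x 3` numeric array (0-255).
#' @return `H x W` numeric matrix.
#' @export
to_gray <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Local binary pattern map
#'
#' Per pixel, compares the P neighbours at radius R with the centre and packs
#' the comparison bits into an integer code:
#' `code = sum_i 2^(i-1) * H(I_i - I_c)`, where the Heaviside step uses the
#' `H(0) = 1` convention (a constant image therefore codes as `2^P - 1`
#' everywhere). Borders are handled by reflect padding. Non-integer neighbour
#' coordinates are rounded to the nearest pixel by default (the classic
#' 8-neighbourhood for P = 8, R = 1); set `interp = "bilinear"` to sample the
#' circle exactly.
#'
#' @param img grayscale matrix (see [to_gray()]).
#' @param P number of neighbours.
#' @param R neighbourhood radius in pixels.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return integer-valued matrix of LBP codes in `[0, 2^P - 1]`, with
#'   attributes `kind`, `P`, `R`.
#' @export
lbp <- function(img, P = 8L, R = 1, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  stopifnot(P >= 1L, R > 0)
  if (min(dim(img)) < 2 * R + 1) stop("image smaller than 2R+1 in one dimension")
  off <- neighbour_offsets(P, R)
  codes <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(P)) {
    ni <- neighbour_value(img, off$dy[i], off$dx[i], interp)
    codes <- codes + 2^(i - 1) * (ni - img >= 0)
  }
  structure(codes, kind = "LBP", P = P, R = R)
}

#' Gradient direction-of-maximum-variation field
#'
#' Computes image gradients `gx`, `gy` (Sobel 3x3 by default, central
#' differences optionally) and the scalar field
#' `G_c = gx * gy / max(|gx|, |gy|, eps)` that modulates the GLBP bits.
#'
#' @param img grayscale matrix.
#' @param operator `"sobel"` or `"central"`.
#' @param eps guard against division by zero.
#' @return list with matrices `gx`, `gy`, `gc`.
#' @export
gradient_direction <- function(img, operator = c("sobel", "central"), eps = 1e-8) {
  operator <- match.arg(operator)
  if (operator == "sobel") {
    gx <- 2 * (shift_reflect(img, 0, 1) - shift_reflect(img, 0, -1)) +
      (shift_reflect(img, -1, 1) - shift_reflect(img, -1, -1)) +
      (shift_reflect(img, 1, 1) - shift_reflect(img, 1, -1))
    gy <- 2 * (shift_reflect(img, 1, 0) - shift_reflect(img, -1, 0)) +
      (shift_reflect(img, 1, 1) - shift_reflect(img, -1, 1)) +
      (shift_reflect(img, 1, -1) - shift_reflect(img, -1, -1))
  } else {
    gx <- (shift_reflect(img, 0, 1) - shift_reflect(img, 0, -1)) / 2
    gy <- (shift_reflect(img, 1, 0) - shift_reflect(img, -1, 0)) / 2
  }
  gc <- gx * gy / pmax(pmax(abs(gx), abs(gy)), eps)
  list(gx = gx, gy = gy, gc = gc)
}

#' Gradient-weighted local binary pattern map
#'
#' LBP variant whose comparison bits are modulated by the gradient
#' direction-of-maximum-variation field evaluated at the neighbour position:
#' `code = sum_i 2^(i-1) * H((I_i - I_c) * G_c(x_i, y_i))`. Where the field is
#' positive at all neighbours the code equals the plain LBP code; sign flips
#' emphasise pixels around strong, obliquely oriented gradients such as the
#' vermilion border.
#'
#' @inheritParams lbp
#' @param operator gradient operator passed to [gradient_direction()].
#' @return integer-valued matrix of GLBP codes with attributes `kind`, `P`, `R`.
#' @export
glbp <- function(img, P = 8L, R = 1, interp = c("nearest", "bilinear"),
                 operator = "sobel") {
  interp <- match.arg(interp)
  stopifnot(P >= 1L, R > 0)
  if (min(dim(img)) < 2 * R + 1) stop("image smaller than 2R+1 in one dimension")
  gc <- gradient_direction(img, operator)$gc
  off <- neighbour_offsets(P, R)
  codes <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(P)) {
    ni <- neighbour_value(img, off$dy[i], off$dx[i], interp)
    gi <- neighbour_value(gc, off$dy[i], off$dx[i], interp)
    codes <- codes + 2^(i - 1) * ((ni - img) * gi >= 0)
  }
  structure(codes, kind = "GLBP", P = P, R = R)
}

#' Build the 5-channel multidimensional input tensor
#'
#' Stacks `[R, G, B, LBP, GLBP]` into an `H x W x 5` array with every channel
#' scaled to `[0, 1]` (RGB by 255, texture codes by `2^P - 1`).
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param P,R,interp,operator texture parameters, see [lbp()] and [glbp()].
#' @return `H x W x 5` numeric array in `[0, 1]`.
#' @export
build_input_tensor <- function(image, P = 8L, R = 1, interp = "nearest",
                               operator = "sobel") {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be H x W x 3")
  g <- to_gray(image)
  out <- array(0, c(d[1], d[2], 5L))
  out[, , 1:3] <- image / 255
  out[, , 4] <- lbp(g, P, R, interp) / (2^P - 1)
  out[, , 5] <- glbp(g, P, R, interp, operator) / (2^P - 1)
  out
}
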