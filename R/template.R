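# Parametric upper-lip geometry. The outline is three cubic Bezier arcs: two
# outer-border arcs meeting at the cupid's-bow notch (labiale superius) and a
# shallow mouth-line arc closing the polygon through the stomion. The same
# construction drives both the canonical template and the synthetic generator.
#
# Coordinates are (x, y) with x = column and y = row (y grows downwards), so
# the outer border of the upper lip has the smaller y values.

bezier_points <- function(p0, p1, p2, p3, t) {
  u <- 1 - t
  cbind(u^3 * p0[1] + 3 * u^2 * t * p1[1] + 3 * u * t^2 * p2[1] + t^3 * p3[1],
        u^3 * p0[2] + 3 * u^2 * t * p1[2] + 3 * u * t^2 * p2[2] + t^3 * p3[2])
}

# Closed upper-lip polygon in a local frame centred on the chelion line.
# width: chelion-to-chelion distance; thickness: vermilion height at the
# philtrum (notch to mouth line at the midline); bow_depth: how far the notch
# sits below the bow peaks; bow_peak_offset: horizontal peak position.
lip_polygon_local <- function(width, thickness, bow_depth, bow_peak_offset,
                              n = 400L) {
  w2 <- width / 2
  sdrop <- 0.15 * thickness              # mouth-line dip at the midline
  a <- thickness - sdrop                 # notch height above the chelion line
  peak <- a + bow_depth
  bpo <- bow_peak_offset
  n1 <- round(0.3 * n); n3 <- n - 2L * n1
  t1 <- seq(0, 1, length.out = n1 + 1L)[-(n1 + 1L)]
  t3 <- seq(0, 1, length.out = n3 + 1L)[-(n3 + 1L)]
  upper_l <- bezier_points(c(-w2, 0), c(-0.45 * w2, -1.05 * peak),
                           c(-0.8 * bpo, -1.35 * peak), c(0, -a), t1)
  upper_r <- bezier_points(c(0, -a), c(0.8 * bpo, -1.35 * peak),
                           c(0.45 * w2, -1.05 * peak), c(w2, 0), t1)
  lower <- bezier_points(c(w2, 0), c(0.45 * w2, 1.4 * sdrop),
                         c(-0.45 * w2, 1.4 * sdrop), c(-w2, 0), t3)
  rbind(upper_l, upper_r, lower)
}

#' Canonical lip template
#'
#' A dense, closed, simple polyline describing an upper-lip outline (outer
#' border with cupid's bow plus mouth line) in a canonical frame of width 2
#' centred at the origin. Used by [correspond()] as the shape prior that turns
#' sparse anatomical landmarks into a complete contour. Custom templates can
#' be loaded from CSV with [read_template()].
#'
#' @param n_vertices number of polyline vertices (>= 200 recommended).
#' @param thickness,bow_depth,bow_peak_offset canonical shape parameters in
#'   template units.
#' @return object of class `lip_template`: list with `contour` (n x 2 matrix,
#'   columns x, y) and `arc` (cumulative normalised arc length per vertex).
#' @export
lip_template <- function(n_vertices = 400L, thickness = 0.55, bow_depth = 0.12,
                         bow_peak_offset = 0.18) {
  contour <- lip_polygon_local(2, thickness, bow_depth, bow_peak_offset,
                               n = n_vertices)
  new_lip_template(contour)
}

new_lip_template <- function(contour) {
  if (nrow(contour) < 10L) stop("template needs at least 10 vertices")
  if (polygon_self_intersects(contour))
    stop("template contour must be simple (non-self-intersecting)")
  seg <- sqrt(rowSums((contour[c(2:nrow(contour), 1L), ] - contour)^2))
  arc <- c(0, cumsum(seg))[seq_len(nrow(contour))]
  arc <- arc / (arc[length(arc)] + seg[length(seg)])
  structure(list(contour = unname(contour), arc = arc), class = "lip_template")
}

# Named anatomical positions on a closed lip outline given as returned by
# lip_polygon_local (vertex 1 = left chelion, upper border first). Extra
# points are spread uniformly by vertex count along each border.
outline_landmarks <- function(poly, n_landmarks = 13L) {
  n <- nrow(poly)
  n1 <- round(0.3 * n)
  i_chl <- 1L                 # left chelion
  i_ls <- n1 + 1L             # cupid's-bow notch (labiale superius)
  i_chr <- 2L * n1 + 1L       # right chelion
  upper_half_l <- poly[2:(i_ls - 1L), , drop = FALSE]
  i_pkl <- 1L + which.min(upper_half_l[, 2])
  upper_half_r <- poly[(i_ls + 1L):(i_chr - 1L), , drop = FALSE]
  i_pkr <- i_ls + which.min(upper_half_r[, 2])
  i_sto <- 2L * n1 + 1L + round((n - 2L * n1) / 2)  # stomion (mouth-line midpoint)
  fixed <- c(chelion_l = i_chl, bow_peak_l = i_pkl, labiale_superius = i_ls,
             bow_peak_r = i_pkr, chelion_r = i_chr, stomion = i_sto)
  n_extra <- n_landmarks - length(fixed)
  if (n_extra < 0L) stop("n_landmarks must be at least ", length(fixed))
  # distribute extras between consecutive fixed points, favouring long gaps
  bounds <- c(fixed, n + 1L)
  gaps <- diff(bounds)
  extra_counts <- floor(n_extra * gaps / sum(gaps))
  left <- n_extra - sum(extra_counts)
  if (left > 0L) {
    ord <- order(gaps - extra_counts * sum(gaps) / n_extra, decreasing = TRUE)
    extra_counts[ord[seq_len(left)]] <- extra_counts[ord[seq_len(left)]] + 1L
  }
  idx <- integer(0); nms <- character(0)
  for (k in seq_along(fixed)) {
    idx <- c(idx, fixed[k]); nms <- c(nms, names(fixed)[k])
    if (extra_counts[k] > 0L) {
      e <- round(seq(bounds[k], bounds[k + 1L],
                     length.out = extra_counts[k] + 2L))[-c(1L, extra_counts[k] + 2L)]
      idx <- c(idx, e)
      nms <- c(nms, paste0("mid_", names(fixed)[k], "_", seq_len(extra_counts[k])))
    }
  }
  pts <- poly[idx, , drop = FALSE]
  rownames(pts) <- nms
  attr(pts, "vertex_idx") <- idx
  pts
}

# Proper-crossing test of every non-adjacent edge pair, vectorised per edge.
polygon_self_intersects <- function(poly, return_pair = FALSE) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- ax[nxt]; by <- ay[nxt]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    d1 <- (bx[js] - ax[js]) * (ay[i] - ay[js]) - (by[js] - ay[js]) * (ax[i] - ax[js])
    d2 <- (bx[js] - ax[js]) * (by[i] - ay[js]) - (by[js] - ay[js]) * (bx[i] - ax[js])
    d3 <- (bx[i] - ax[i]) * (ay[js] - ay[i]) - (by[i] - ay[i]) * (ax[js] - ax[i])
    d4 <- (bx[i] - ax[i]) * (by[js] - ay[i]) - (by[i] - ay[i]) * (bx[js] - ax[i])
    hit <- which(d1 * d2 < 0 & d3 * d4 < 0)
    if (length(hit)) {
      if (return_pair) return(c(i, js[hit[1L]]))
      return(TRUE)
    }
  }
  if (return_pair) return(NULL)
  FALSE
}
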