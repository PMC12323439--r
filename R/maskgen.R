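# Mask generation: sparse ordered landmarks -> template correspondence ->
# contour densification -> shape-preserving projection -> rasterised mask.

# 2D similarity Procrustes (translation, rotation, isotropic scale; no
# reflection). Returns the transform mapping `from` onto `to`.
similarity_fit <- function(from, to) {
  mf <- colMeans(from); mt <- colMeans(to)
  A <- t(sweep(to, 2, mt)) %*% sweep(from, 2, mf)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, d))
  R <- sv$u %*% S %*% t(sv$v)
  denom <- sum(sweep(from, 2, mf)^2)
  s <- sum(diag(S) * sv$d) / denom
  list(R = R, s = s, from_center = mf, to_center = mt)
}

apply_similarity <- function(tr, pts) {
  sweep(tr$s * sweep(pts, 2, tr$from_center) %*% t(tr$R), 2, tr$to_center, "+")
}

# Optimal monotone circular assignment of landmarks to template vertices,
# minimising the summed squared distances. cost: N x V matrix.
monotone_assign <- function(cost) {
  N <- nrow(cost); V <- ncol(cost)
  if (N > V) stop("more landmarks than template vertices")
  best <- Inf; best_s <- NA_integer_
  dp_run <- function(s, keep_ptr = FALSE) {
    w <- ((s + seq_len(V - 1L) - 1L) %% V) + 1L   # window vertex ids after s
    g <- rep(Inf, V - 1L)
    ptr <- if (keep_ptr) matrix(NA_integer_, N, V - 1L)
    base <- cost[1L, s]
    for (i in 2:N) {
      cm <- cummin(g)
      prev_best <- c(base, cm[-(V - 1L)])
      prev_best <- pmin(prev_best, base)
      if (keep_ptr) {
        am <- integer(V - 1L)
        bi <- 0L; bv <- base   # 0 encodes "landmark i-1 at start vertex s"
        for (k in seq_len(V - 1L)) {
          am[k] <- bi
          if (is.finite(g[k]) && g[k] < bv) { bv <- g[k]; bi <- k }
        }
        ptr[i, ] <- am
      }
      g <- cost[i, w] + prev_best
      base <- Inf
    }
    list(cost = min(g), g = g, w = w, ptr = ptr)
  }
  # starts are scanned cheapest-first so the lower bound prunes most of them
  for (s in order(cost[1L, ])) {
    if (cost[1L, s] >= best) break
    r <- dp_run(s)
    if (r$cost < best) { best <- r$cost; best_s <- s }
  }
  r <- dp_run(best_s, keep_ptr = TRUE)
  idx <- integer(N)
  k <- which.min(r$g)
  idx[N] <- r$w[k]
  for (i in N:2) {
    k <- r$ptr[i, k]
    idx[i - 1L] <- if (k == 0L) best_s else r$w[k]
  }
  list(vertex_idx = idx, cost = best, start = best_s)
}

#' Correspond sparse landmarks to template points
#'
#' Similarity-aligns the lip template to the ordered landmarks (iterated
#' closest-point refinement of a closed-form 2D Procrustes fit, reflections
#' excluded) and then assigns each landmark the nearest template vertex under
#' a monotone-ordering constraint along the contour, minimising the summed
#' squared distances among all monotone circular assignments.
#'
#' @param landmarks `N x 2` matrix of ordered pixel coordinates (N >= 3,
#'   consecutive points distinct, traversing the contour monotonically).
#' @param template a [lip_template()].
#' @param reorder if `TRUE`, mis-ordered landmarks (detected by a
#'   self-intersecting landmark polygon) are re-sorted along the contour
#'   instead of raising an error.
#' @param iters alignment/assignment refinement iterations.
#' @return object of class `lip_correspondence`: the matched template points
#'   `points` (N x 2, image frame), their `vertex_idx` on the template, the
#'   fully `aligned` template contour and the fitted `transform`.
#' @export
correspond <- function(landmarks, template = lip_template(), reorder = FALSE,
                       iters = 3L) {
  landmarks <- validate_landmarks(landmarks)
  N <- nrow(landmarks)
  V <- nrow(template$contour)
  ctr <- template$contour
  # initial alignment: the landmarks are ordered along the contour, so pair
  # them with template points at matching arc-length fractions; search the
  # circular offset and keep the similarity fit with the lowest residual
  seg <- sqrt(rowSums((landmarks[c(2:N, 1L), , drop = FALSE] - landmarks)^2))
  lfrac <- c(0, cumsum(seg))[seq_len(N)] / sum(seg)
  best <- Inf; tr <- NULL
  for (o in seq(0, 1 - 1 / 72, by = 1 / 72)) {
    vi <- pmin(V, findInterval((o + lfrac) %% 1, template$arc) + 1L)
    cand <- similarity_fit(ctr[vi, , drop = FALSE], landmarks)
    res <- sum((apply_similarity(cand, ctr[vi, , drop = FALSE]) - landmarks)^2)
    if (res < best) { best <- res; tr <- cand }
  }
  aligned <- apply_similarity(tr, ctr)
  prj <- NULL
  for (it in seq_len(iters)) {
    cost <- outer(landmarks[, 1], aligned[, 1], "-")^2 +
            outer(landmarks[, 2], aligned[, 2], "-")^2
    asg <- monotone_assign(cost)
    prj <- project_feet(landmarks, aligned, asg$vertex_idx)
    # refit on canonical-frame feet so the transform stays exact
    feet0 <- contour_point_at(ctr, prj$pos)
    tr <- similarity_fit(feet0, landmarks)
    aligned <- apply_similarity(tr, ctr)
  }
  # polish: alternate projection and refit with the assignment carried over
  # (the expensive monotone reassignment above has stabilised by now); this
  # drives coincident landmarks to an exact fit
  prev <- Inf
  for (it in seq_len(80L)) {
    vidx <- (round(prj$pos) - 1L) %% V + 1L
    prj <- project_feet(landmarks, aligned, vidx)
    res <- sum((prj$points - landmarks)^2)
    tr <- similarity_fit(contour_point_at(ctr, prj$pos), landmarks)
    aligned <- apply_similarity(tr, ctr)
    if (res < 1e-18 || prev - res < 1e-15) break
    prev <- res
  }
  cost <- outer(landmarks[, 1], aligned[, 1], "-")^2 +
          outer(landmarks[, 2], aligned[, 2], "-")^2
  asg <- monotone_assign(cost)
  # mis-ordered input (e.g. a swapped pair) makes the landmark polygon cross
  # itself; a correctly ordered traversal of the lip contour never does
  if (polygon_self_intersects(landmarks)) {
    if (!reorder) stop("landmarks are not ordered along the contour; ",
                       "pass reorder = TRUE to re-sort them")
    un <- apply(cost, 1, which.min)
    ord <- order(((un - un[1]) %% V))
    landmarks <- landmarks[ord, , drop = FALSE]
    cost <- cost[ord, , drop = FALSE]
    asg <- monotone_assign(cost)
  }
  prj <- project_feet(landmarks, aligned, asg$vertex_idx)
  structure(list(landmarks = landmarks,
                 points = prj$points,
                 vertex_idx = asg$vertex_idx,
                 pos = prj$pos,
                 aligned = aligned,
                 arc = template$arc,
                 transform = tr),
            class = "lip_correspondence")
}

# Refine a vertex assignment to exact feet on the contour polyline: each
# landmark is projected onto the two edges adjacent to its assigned vertex.
# `pos` is the continuous (1-based, modulo-V) vertex coordinate of the foot.
project_feet <- function(P, contour, vidx) {
  V <- nrow(contour)
  pts <- matrix(0, nrow(P), 2L)
  pos <- numeric(nrow(P))
  halfwin <- 3L
  for (i in seq_len(nrow(P))) {
    v <- vidx[i]
    ids <- ((v - 1L + (-halfwin):halfwin) %% V) + 1L
    pr <- project_point_polyline(P[i, ], contour[ids, , drop = FALSE])
    pts[i, ] <- pr$point
    pos[i] <- ((v - 1L - halfwin + pr$frac * 2 * halfwin) %% V) + 1
  }
  list(points = pts, pos = pos)
}

# point on the contour polyline at continuous vertex coordinate `pos`
contour_point_at <- function(contour, pos) {
  V <- nrow(contour)
  a <- floor(pos - 1) %% V + 1
  t <- (pos - 1) %% 1
  b <- (a %% V) + 1
  contour[a, , drop = FALSE] * (1 - t) + contour[b, , drop = FALSE] * t
}

validate_landmarks <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L) stop("landmarks must be an N x 2 matrix")
  if (nrow(landmarks) < 3L) stop("at least 3 landmarks are required")
  d <- sqrt(rowSums((landmarks[c(2:nrow(landmarks), 1L), ] - landmarks)^2))
  if (any(d[-length(d)] == 0)) stop("consecutive landmarks must be distinct")
  ctr <- sweep(landmarks, 2, colMeans(landmarks))
  ev <- svd(ctr)$d
  if (ev[2] < 1e-9 * max(ev[1], 1)) stop("landmarks are collinear")
  landmarks
}

# Ordered up to small local jitter: projection onto a dense polyline can move
# a correctly ordered landmark backwards by a vertex or two, so only backward
# steps larger than ~2% of the contour count as a genuine ordering violation.
circularly_monotone <- function(idx, V, tol = ceiling(V / 50)) {
  r <- (idx - idx[1]) %% V
  all(diff(r) >= -tol)
}

#' Densify the template between corresponding points
#'
#' For each consecutive pair of corresponding template points and each
#' interpolation parameter `a` on a uniform grid in (0, 1), finds the
#' template-contour point closest to the chord point
#' `(1 - a) T_i + a T_{i+1}`, restricted to the template arc between the two
#' points (projection of the chord point onto the curve). Also records each
#' interpolated point's along-chord fraction and signed normal deviation from
#' the chord, which [project_to_trajectory()] uses to transfer the template's
#' local shape.
#'
#' @param corr a [correspond()] result.
#' @param pts_per_segment interpolated points per landmark segment (K per
#'   segment; 0 yields the bare landmark polygon).
#' @return data frame with one row per interpolated point: `segment`, `a`,
#'   `x`, `y`, `u` (chord fraction), `d` (signed normal deviation), `t_ratio`
#'   (distance-ratio parameter) and `arc_pos`.
#' @export
discretize_template <- function(corr, pts_per_segment = 10L) {
  stopifnot(pts_per_segment >= 0L)
  if (pts_per_segment == 0L)
    return(data.frame(segment = integer(0), a = numeric(0), x = numeric(0),
                      y = numeric(0), u = numeric(0), d = numeric(0),
                      t_ratio = numeric(0), arc_pos = numeric(0)))
  N <- nrow(corr$points)
  V <- nrow(corr$aligned)
  agrid <- seq_len(pts_per_segment) / (pts_per_segment + 1)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    j <- if (i == N) 1L else i + 1L
    Ti <- corr$points[i, ]; Tj <- corr$points[j, ]
    p0 <- corr$pos[i]; p1 <- corr$pos[j]
    if (p1 <= p0) {
      # small inversions are projection jitter around coincident feet; only a
      # genuine wrap (the closing segment) spans the template seam
      if (p0 - p1 < V / 2) p1 <- p0 + 1e-6 else p1 <- p1 + V
    }
    inner <- seq_len(V * 2)
    inner <- inner[inner > p0 & inner < p1]
    arc_ids <- ((inner - 1L) %% V) + 1L              # vertices strictly inside
    arcpts <- rbind(Ti, corr$aligned[arc_ids, , drop = FALSE], Tj)
    rows <- lapply(agrid, function(a) {
      q <- (1 - a) * Ti + a * Tj
      pr <- project_point_polyline(q, arcpts)
      chord <- Tj - Ti
      clen2 <- sum(chord^2)
      if (clen2 > 1e-18) {
        u <- sum((pr$point - Ti) * chord) / clen2
        nrm <- c(-chord[2], chord[1]) / sqrt(clen2)
        d <- sum((pr$point - Ti) * nrm)
      } else {
        # coincident corresponding points (very thin or degenerate arcs):
        # fall back to plain chord interpolation
        u <- a; d <- 0
      }
      dTi <- sqrt(sum((pr$point - Ti)^2))
      dTj <- sqrt(sum((pr$point - Tj)^2))
      data.frame(segment = i, a = a, x = pr$point[1], y = pr$point[2], u = u,
                 d = d, t_ratio = dTi / (dTi + dTj), arc_pos = i + pr$frac)
    })
    seg <- do.call(rbind, rows)
    # projections onto a curved arc are almost always ordered; enforce it
    seg <- seg[order(seg$arc_pos), , drop = FALSE]
    seg$a <- agrid
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

# nearest point on an open polyline; frac is the normalised position in (0,1)
project_point_polyline <- function(q, pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(point = pts[1, ], frac = 0))
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  bx <- pts[-1, 1]; by <- pts[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  t <- pmin(pmax(((q[1] - ax) * dx + (q[2] - ay) * dy) / len2, 0), 1)
  px <- ax + t * dx; py <- ay + t * dy
  d2 <- (px - q[1])^2 + (py - q[2])^2
  k <- which.min(d2)
  list(point = c(px[k], py[k]), frac = (k - 1 + t[k]) / (n - 1))
}

#' Project interpolated template points onto the landmark trajectory
#'
#' Places the interpolated anatomical landmarks `A_j` between consecutive
#' observed landmarks. In `"ratio"` mode each point is placed on the landmark
#' trajectory (straight chord or periodic cubic spline through the
#' landmarks) at the arc-length fraction given by its distance ratio to the
#' two bounding template points, which zeroes the proportional-distance
#' mismatch while staying closest to the bounding landmark. In
#' `"chord_frame"` mode (default) the template point's chord-frame
#' coordinates (along-chord fraction and signed normal deviation, scaled by
#' the chord-length ratio) are transferred to the landmark chord, carrying
#' the template's local shape -- in particular the cupid's bow -- into the
#' gaps between landmarks.
#'
#' @param corr a [correspond()] result.
#' @param interp output of [discretize_template()].
#' @param mode `"chord_frame"` or `"ratio"`.
#' @param trajectory `"polyline"` or `"spline"` (ratio mode only).
#' @return matrix of interpolated landmark coordinates (rows ordered along
#'   the contour) with attribute `segment`.
#' @export
project_to_trajectory <- function(corr, interp,
                                  mode = c("chord_frame", "ratio"),
                                  trajectory = c("polyline", "spline")) {
  mode <- match.arg(mode)
  trajectory <- match.arg(trajectory)
  P <- corr$landmarks
  N <- nrow(P)
  if (nrow(interp) == 0L)
    return(structure(matrix(numeric(0), 0, 2), segment = integer(0)))
  nxt <- c(2:N, 1L)
  chord <- P[nxt, , drop = FALSE] - P
  clen <- sqrt(rowSums(chord^2))
  if (any(clen == 0)) stop("duplicate consecutive landmarks: pair ",
                           which(clen == 0)[1])
  tchord <- corr$points[nxt, , drop = FALSE] - corr$points
  tclen <- sqrt(rowSums(tchord^2))
  sp <- NULL
  if (mode == "ratio" && trajectory == "spline") {
    s <- c(0, cumsum(clen))
    xs <- c(P[, 1], P[1, 1]); ys <- c(P[, 2], P[1, 2])
    sp <- list(fx = splinefun(s, xs, method = "periodic"),
               fy = splinefun(s, ys, method = "periodic"),
               s = s)
  }
  A <- matrix(0, nrow(interp), 2L)
  for (r in seq_len(nrow(interp))) {
    i <- interp$segment[r]
    if (mode == "chord_frame") {
      sc <- if (tclen[i] > 1e-9) clen[i] / tclen[i] else 0
      nrm <- c(-chord[i, 2], chord[i, 1]) / clen[i]
      A[r, ] <- P[i, ] + interp$u[r] * chord[i, ] + interp$d[r] * sc * nrm
    } else {
      t <- interp$t_ratio[r]
      if (trajectory == "polyline") {
        A[r, ] <- P[i, ] + t * chord[i, ]
      } else {
        at <- sp$s[i] + t * clen[i]
        A[r, ] <- c(sp$fx(at), sp$fy(at))
      }
    }
  }
  structure(A, segment = interp$segment)
}

#' Assemble the full contour and rasterize it to a binary mask
#'
#' Interleaves the anatomical landmarks with the interpolated landmarks in
#' contour order, verifies the polygon is closed and simple, and fills it
#' with the even-odd rule at integer pixel centres (0-based x = column,
#' y = row; a pixel is foreground when its centre lies inside the polygon,
#' with half-open boundaries towards larger coordinates).
#'
#' @param landmarks `N x 2` landmark matrix.
#' @param A interpolated landmarks from [project_to_trajectory()].
#' @param shape `c(H, W)` output mask size in pixels.
#' @return `H x W` binary matrix (attribute `contour` holds the polygon).
#' @export
assemble_and_rasterize <- function(landmarks, A, shape) {
  poly <- interleave_contour(landmarks, A)
  cross <- polygon_self_intersects(poly, return_pair = TRUE)
  if (!is.null(cross))
    stop("assembled contour self-intersects (segments ", cross[1], " and ",
         cross[2], ")")
  m <- rasterize_polygon(poly, shape)
  if (sum(m) == 0) warning("contour lies entirely outside the frame")
  attr(m, "contour") <- poly
  m
}

interleave_contour <- function(landmarks, A) {
  N <- nrow(landmarks)
  seg <- attr(A, "segment")
  if (is.null(seg)) seg <- rep(seq_len(N), length.out = nrow(A))
  out <- vector("list", N)
  for (i in seq_len(N))
    out[[i]] <- rbind(landmarks[i, , drop = FALSE],
                      A[seg == i, , drop = FALSE])
  unname(do.call(rbind, out))
}

#' Rasterize a closed polygon with the even-odd rule
#'
#' @param poly `n x 2` matrix of (x, y) vertices, 0-based pixel-centre
#'   coordinates.
#' @param shape `c(H, W)`.
#' @return `H x W` matrix of 0/1.
#' @export
rasterize_polygon <- function(poly, shape) {
  H <- shape[1]; W <- shape[2]
  m <- matrix(0, H, W)
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- x1[nxt]; y2 <- y1[nxt]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  for (y in max(0, ceiling(min(ylo))):min(H - 1, floor(max(yhi)))) {
    act <- which(ylo <= y & y < yhi)                  # half-open in y
    if (length(act) == 0L) next
    xs <- sort(x1[act] + (y - y1[act]) * (x2[act] - x1[act]) / (y2[act] - y1[act]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      xa <- ceiling(xs[k]); xb <- ceiling(xs[k + 1L]) - 1L  # half-open in x
      if (xb < 0 || xa > W - 1) next
      xa <- max(xa, 0L); xb <- min(xb, W - 1L)
      if (xa <= xb) m[y + 1L, (xa:xb) + 1L] <- 1
    }
  }
  m
}

#' Generate a segmentation mask from sparse landmarks
#'
#' End-to-end mask generation: correspond the template ([correspond()]),
#' densify it ([discretize_template()]), project the interpolated points onto
#' the landmark trajectory ([project_to_trajectory()]) and rasterize the
#' assembled contour ([assemble_and_rasterize()]).
#'
#' @param landmarks `N x 2` ordered landmark matrix (pixel coordinates).
#' @param shape output `c(H, W)`.
#' @param template a [lip_template()].
#' @param pts_per_segment interpolated points per landmark segment.
#' @param mode,trajectory see [project_to_trajectory()].
#' @param reorder see [correspond()].
#' @return binary mask with the assembled contour as attribute `contour`.
#' @export
generate_mask_from_landmarks <- function(landmarks, shape,
                                         template = lip_template(),
                                         pts_per_segment = 10L,
                                         mode = "chord_frame",
                                         trajectory = "polyline",
                                         reorder = FALSE) {
  corr <- correspond(landmarks, template, reorder = reorder)
  interp <- discretize_template(corr, pts_per_segment)
  A <- project_to_trajectory(corr, interp, mode, trajectory)
  assemble_and_rasterize(corr$landmarks, A, shape)
}
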