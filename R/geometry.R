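# Planar polygon primitives for forest-unit and NEA layers.
#
# A polygon ring is a two-column numeric matrix (x, y) of vertices in a
# projected CRS (meters); the closing vertex may be present or absent. Rings
# here are simple (non-self-intersecting) and without holes, which covers
# forest-unit and NEA geometries. Where an operation is only exact for
# convex rings (clipping, dilation) this is stated and enforced.

ring_close <- function(ring) {
  ring <- as.matrix(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], tolerance = 1e-12)))
    ring <- rbind(ring, ring[1, ])
  ring
}

ring_open <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1 &&
      isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], tolerance = 1e-12)))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

poly_signed_area <- function(ring) {
  r <- ring_open(ring)
  n <- nrow(r)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * sum(r[, 1] * r[j, 2] - r[j, 1] * r[, 2])
}

#' Polygon area (shoelace formula)
#'
#' @param ring two-column matrix of vertices (m).
#' @return area in m^2 (always >= 0).
#' @export
poly_area <- function(ring) abs(poly_signed_area(ring))

ring_ccw <- function(ring) {
  r <- ring_open(ring)
  if (poly_signed_area(r) < 0) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
  r
}

#' Point-in-polygon test
#'
#' Even-odd ray casting; points on the boundary count as inside.
#'
#' @param px,py point coordinates (vectorized).
#' @param ring polygon ring.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  r <- ring_open(ring)
  n <- nrow(r)
  xs <- r[, 1]; ys <- r[, 2]
  out <- logical(length(px))
  for (q in seq_along(px)) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
      # boundary check
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-9 &&
          x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
          y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    out[q] <- on_edge || inside
  }
  out
}

is_convex_ring <- function(ring, tol = 1e-9) {
  r <- ring_ccw(ring)
  n <- nrow(r)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  nx2 <- c(3:n, 1, 2)
  cr <- (r[nxt, 1] - r[, 1]) * (r[nx2, 2] - r[nxt, 2]) -
        (r[nxt, 2] - r[, 2]) * (r[nx2, 1] - r[nxt, 1])
  scale <- max(abs(r)) + 1
  all(cr >= -tol * scale * scale)
}

#' Convex hull (Andrew's monotone chain)
#'
#' @param points two-column matrix.
#' @return hull ring (CCW, not closed).
#' @export
convex_hull <- function(points) {
  p <- unique(as.matrix(points))
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  n <- nrow(p)
  if (n <= 2) return(p)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(p[h[length(h) - 1], ], p[h[length(h)], ], p[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  p[hull, , drop = FALSE]
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' Computes the intersection of `subject` with the *convex* ring `clip`.
#' Forest-unit fragments across survey revisions are obtained this way; the
#' convexity requirement of the clip ring is checked.
#'
#' @param subject polygon ring (any simple polygon).
#' @param clip convex polygon ring.
#' @return intersection ring (possibly with zero area), or `NULL` when the
#'   intersection is empty.
#' @export
clip_polygon <- function(subject, clip) {
  clip <- ring_ccw(clip)
  if (!is_convex_ring(clip))
    stop("clip_polygon requires a convex clip ring")
  out <- ring_open(subject)
  nclip <- nrow(clip)
  for (e in seq_len(nclip)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nclip) 1 else e + 1, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    isect <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d2[1] * d1[2] - d2[2] * d1[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / -den
      c(p[1] + t * d1[1], p[2] + t * d1[2])
    }
    n <- nrow(out)
    res <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- out[i, ]; prv <- out[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) res <- rbind(res, isect(prv, cur))
        res <- rbind(res, cur)
      } else if (pi) {
        res <- rbind(res, isect(prv, cur))
      }
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3 || poly_area(out) <= 0) return(NULL)
  out
}

#' Dilate a polygon by a fixed width with round joins
#'
#' Minkowski sum of the ring with a disc of radius `width`, with circular
#' arcs (round joins) at the vertices approximated by `arc_segments` chords
#' per quarter turn. Exact for convex rings; a non-convex ring is first
#' replaced by its convex hull with a warning (no general polygon-offset
#' engine is shipped). A degenerate ring (< 3 distinct vertices or zero
#' area) is repaired to its convex hull before dilation, mirroring a
#' zero-width buffer repair.
#'
#' For a convex ring of area A and perimeter P the dilated area converges to
#' `A + P*width + pi*width^2` as `arc_segments` grows.
#'
#' @param ring polygon ring.
#' @param width buffer width in m (>= 0).
#' @param arc_segments chords per quarter circle (default 24).
#' @return dilated ring (CCW).
#' @export
buffer_polygon <- function(ring, width, arc_segments = 24) {
  stopifnot(width >= 0)
  r <- ring_ccw(ring)
  if (nrow(unique(r)) < 3 || poly_area(r) <= 0) {
    warning("degenerate ring repaired via convex hull before dilation")
    r <- convex_hull(r)
    if (nrow(r) < 3) {
      # collapsed to a segment or point: dilate to a capsule / disc
      if (width <= 0) stop("cannot repair degenerate ring")
      a <- r[1, ]
      b <- if (nrow(r) == 2) r[2, ] else r[1, ] + c(1e-9, 0)
      ang0 <- atan2(b[2] - a[2], b[1] - a[1]) + pi / 2
      k <- 2 * arc_segments
      t1 <- ang0 + pi * (0:k) / k
      t2 <- ang0 + pi + pi * (0:k) / k
      return(rbind(cbind(a[1] + width * cos(t1), a[2] + width * sin(t1)),
                   cbind(b[1] + width * cos(t2), b[2] + width * sin(t2))))
    }
  }
  if (!is_convex_ring(r)) {
    warning("non-convex ring: dilating its convex hull")
    r <- ring_ccw(convex_hull(r))
  }
  if (width == 0) return(r)
  n <- nrow(r)
  prv <- c(n, seq_len(n - 1))
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    # outward normals of incoming and outgoing edges (CCW ring)
    e_in <- r[i, ] - r[prv[i], ]
    e_out <- r[if (i == n) 1 else i + 1, ] - r[i, ]
    a_in <- atan2(-e_in[1], e_in[2])    # outward normal angle, incoming edge
    a_out <- atan2(-e_out[1], e_out[2])
    sweep <- (a_out - a_in) %% (2 * pi)
    k <- max(1L, ceiling(sweep / (pi / 2) * arc_segments))
    ang <- a_in + sweep * (0:k) / k
    out <- rbind(out, cbind(r[i, 1] + width * cos(ang),
                            r[i, 2] + width * sin(ang)))
  }
  out
}

dist_point_ring <- function(px, py, ring) {
  r <- ring_close(ring)
  n <- nrow(r) - 1
  d2 <- Inf
  for (i in seq_len(n)) {
    x1 <- r[i, 1]; y1 <- r[i, 2]; x2 <- r[i + 1, 1]; y2 <- r[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / len2))
         else 0
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d2 <- min(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

#' Pole of inaccessibility of a polygon
#'
#' The interior point farthest from the polygon boundary, found by iterative
#' grid refinement (quadtree subdivision of candidate cells, best-first) to
#' a given precision. Used to pick the "main" overlap fragment when matching
#' forest units across survey revisions.
#'
#' @param ring polygon ring.
#' @param precision search precision in m (default 0.1).
#' @return named numeric `c(x, y, dist)` where `dist` is the clearance to
#'   the boundary.
#' @export
pole_of_inaccessibility <- function(ring, precision = 0.1) {
  r <- ring_open(ring)
  stopifnot(nrow(r) >= 3)
  signed_dist <- function(x, y) {
    d <- dist_point_ring(x, y, r)
    if (point_in_polygon(x, y, r)) d else -d
  }
  xmin <- min(r[, 1]); xmax <- max(r[, 1])
  ymin <- min(r[, 2]); ymax <- max(r[, 2])
  size <- min(xmax - xmin, ymax - ymin)
  h0 <- if (size > 0) size / 2 else max(xmax - xmin, ymax - ymin) / 2
  if (h0 <= 0) return(c(x = r[1, 1], y = r[1, 2], dist = 0))
  # initial square cover
  cells <- list()
  x <- xmin
  while (x < xmax) {
    y <- ymin
    while (y < ymax) {
      cells[[length(cells) + 1]] <- c(x + h0 / 2, y + h0 / 2, h0 / 2)
      y <- y + h0
    }
    x <- x + h0
  }
  score <- function(cell) signed_dist(cell[1], cell[2])
  best <- c(mean(r[, 1]), mean(r[, 2]))
  best_d <- signed_dist(best[1], best[2])
  pot <- vapply(cells, function(cl) score(cl) + cl[3] * sqrt(2), 0)
  while (length(cells)) {
    k <- which.max(pot)
    cell <- cells[[k]]
    cell_d <- pot[k] - cell[3] * sqrt(2)
    cells[[k]] <- NULL
    pot <- pot[-k]
    if (cell_d > best_d) {
      best <- cell[1:2]
      best_d <- cell_d
    }
    if ((cell_d + cell[3] * sqrt(2)) - best_d <= precision) next
    h <- cell[3] / 2
    if (h < precision / 4) next
    for (dx in c(-h, h)) for (dy in c(-h, h)) {
      nc <- c(cell[1] + dx, cell[2] + dy, h)
      cells[[length(cells) + 1]] <- nc
      pot <- c(pot, score(nc) + h * sqrt(2))
    }
  }
  c(x = best[1], y = best[2], dist = best_d)
}
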