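# Planar polygon primitives.
#
# A polygon is stored as a list of "parts", each part a numeric matrix with
# two columns (x, y) holding the vertices of one ring in order. Rings may be
# given open or closed; they are normalised to open form. Holes are not
# supported: multi-part polygons are treated as disjoint unions of their
# parts (point-in-polygon uses even-odd counting across parts, so the
# representation degrades gracefully if parts overlap).

normalise_ring <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop("polygon ring must be a numeric matrix with two columns", call. = FALSE)
  }
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("polygon ring needs at least three distinct vertices", call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# Accepts a single matrix or a list of matrices; returns a list of rings.
normalise_polygon <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) p <- list(p)
  lapply(p, normalise_ring)
}

ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(parts) sum(vapply(parts, function(r) abs(ring_signed_area(r)), 0))

ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Area-weighted centroid over parts.
polygon_centroid <- function(parts) {
  areas <- vapply(parts, function(r) abs(ring_signed_area(r)), 0)
  cents <- vapply(parts, ring_centroid, numeric(2L))
  if (sum(areas) == 0) return(rowMeans(cents))
  c(cents %*% (areas / sum(areas)))
}

polygon_bbox <- function(parts) {
  xs <- unlist(lapply(parts, function(r) r[, 1L]))
  ys <- unlist(lapply(parts, function(r) r[, 2L]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Even-odd ray casting, vectorised over points; `pts` is an n x 2 matrix.
points_in_ring <- function(pts, ring) {
  px <- pts[, 1L]; py <- pts[, 2L]
  nv <- nrow(ring)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

points_in_polygon <- function(pts, parts) {
  pts <- as.matrix(pts)
  bb <- polygon_bbox(parts)
  cand <- pts[, 1L] >= bb["xmin"] & pts[, 1L] <= bb["xmax"] &
    pts[, 2L] >= bb["ymin"] & pts[, 2L] <= bb["ymax"]
  out <- logical(nrow(pts))
  if (!any(cand)) return(out)
  sub <- pts[cand, , drop = FALSE]
  hit <- logical(nrow(sub))
  for (ring in parts) hit <- xor(hit, points_in_ring(sub, ring))
  out[cand] <- hit
  out
}

#' Rectangular polygon ring
#'
#' Convenience constructor for an axis-aligned rectangle, handy for toy
#' tessellations and examples.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @return A 4 x 2 vertex matrix.
#' @export
rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Sutherland-Hodgman clip of a convex ring against the half-plane
# {z : a*z_x + b*z_y <= c}.
clip_halfplane <- function(ring, a, b, cc) {
  n <- nrow(ring)
  vals <- a * ring[, 1L] + b * ring[, 2L] - cc
  keep_any <- any(vals <= 0)
  if (!keep_any) return(NULL)
  if (all(vals <= 0)) return(ring)
  out_x <- numeric(0); out_y <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    vi <- vals[i]; vj <- vals[j]
    if (vj <= 0) {
      out_x <- c(out_x, ring[j, 1L]); out_y <- c(out_y, ring[j, 2L])
    }
    if ((vi <= 0) != (vj <= 0)) {
      t <- vj / (vj - vi)
      out_x <- c(out_x, ring[j, 1L] + t * (ring[i, 1L] - ring[j, 1L]))
      out_y <- c(out_y, ring[j, 2L] + t * (ring[i, 2L] - ring[j, 2L]))
    }
    j <- i
  }
  if (length(out_x) < 3L) return(NULL)
  cbind(out_x, out_y)
}

# Voronoi cell of seed i within a rectangular domain, by successive
# half-plane clipping against the perpendicular bisectors with other seeds.
voronoi_cell <- function(seeds, i, domain) {
  ring <- rect_ring(domain[1L], domain[2L], domain[3L], domain[4L])
  si <- seeds[i, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == i) next
    sj <- seeds[j, ]
    a <- sj[1L] - si[1L]; b <- sj[2L] - si[2L]
    cc <- sum((sj^2 - si^2)) / 2
    ring <- clip_halfplane(ring, a, b, cc)
    if (is.null(ring)) stop("empty Voronoi cell (duplicated seeds?)", call. = FALSE)
  }
  dimnames(ring) <- NULL
  ring
}

# Representative interior point of a polygon: the area-weighted centroid
# when it lies inside (always true for convex cells), otherwise the first
# hit of a fine probe lattice over the bounding box.
interior_point <- function(parts, spacing) {
  cen <- matrix(polygon_centroid(parts), 1L, 2L)
  if (points_in_polygon(cen, parts)) return(cen)
  bb <- polygon_bbox(parts)
  step <- max(min(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]) / 20,
              spacing / 100)
  xs <- seq(bb["xmin"] + step / 2, bb["xmax"], by = step)
  ys <- seq(bb["ymin"] + step / 2, bb["ymax"], by = step)
  probe <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  hit <- which(points_in_polygon(probe, parts))
  if (!length(hit)) stop("could not locate an interior point of a unit", call. = FALSE)
  probe[hit[1L], , drop = FALSE]
}

# Squared-distance free pairwise Euclidean distances between two point sets.
pair_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}
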