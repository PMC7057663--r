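#' Build a table of areal units
#'
#' Areal units are the polygons over which the outcome (coarse partition)
#' and the covariate (fine partition) are observed as spatial averages.
#' Units live in a projected planar coordinate system with metre units;
#' geographic (longitude/latitude) coordinates are rejected because all
#' model distances are Euclidean.
#'
#' @param id Character vector of unit identifiers, unique within each
#'   partition.
#' @param partition Character vector, each element `"coarse"` or `"fine"`.
#' @param geometry List of polygons, one per unit. A polygon is a two-column
#'   vertex matrix, or a list of such matrices for multi-part units.
#' @return A tibble with columns `id`, `partition`, `geometry` (list of
#'   normalised ring lists) and `area` (m^2).
#' @examples
#' sq <- rect_ring(0, 1000, 0, 1000)
#' units <- area_units("A", "coarse", list(sq))
#' units$area  # 1e6
#' @export
area_units <- function(id, partition, geometry) {
  id <- as.character(id)
  partition <- as.character(partition)
  if (!all(partition %in% c("coarse", "fine"))) {
    stop("`partition` entries must be \"coarse\" or \"fine\"", call. = FALSE)
  }
  n <- length(id)
  if (length(partition) == 1L) partition <- rep(partition, n)
  if (length(geometry) != n || length(partition) != n) {
    stop("`id`, `partition` and `geometry` must have matching lengths", call. = FALSE)
  }
  geometry <- lapply(geometry, normalise_polygon)
  check_planar_metric(geometry)
  area <- vapply(geometry, polygon_area, 0)
  if (any(area <= 0)) {
    stop("units with non-positive area: ", paste(id[area <= 0], collapse = ", "),
         call. = FALSE)
  }
  for (p in unique(partition)) {
    ids <- id[partition == p]
    if (anyDuplicated(ids)) {
      stop("duplicated unit ids in partition ", p, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(id = id, partition = partition, geometry = geometry, area = area)
}

# Coordinates that all fit inside [-180, 180] x [-90, 90] are almost surely
# geographic; the model needs planar metres.
check_planar_metric <- function(geometry) {
  bb <- units_bbox_list(geometry)
  looks_geo <- bb["xmin"] >= -180 && bb["xmax"] <= 180 &&
    bb["ymin"] >= -90 && bb["ymax"] <= 90
  if (looks_geo) {
    stop("coordinates look geographic (lon/lat); supply a projected CRS in metres",
         call. = FALSE)
  }
  invisible(TRUE)
}

units_bbox_list <- function(geometry) {
  bbs <- vapply(geometry, polygon_bbox, numeric(4L))
  c(xmin = min(bbs[1L, ]), xmax = max(bbs[2L, ]),
    ymin = min(bbs[3L, ]), ymax = max(bbs[4L, ]))
}

units_bbox <- function(units) units_bbox_list(units$geometry)

domain_diameter <- function(units) {
  bb <- units_bbox(units)
  sqrt((bb["xmax"] - bb["xmin"])^2 + (bb["ymax"] - bb["ymin"])^2)[[1L]]
}

#' Unit centroids
#'
#' Area-weighted polygon centroids (centroid of the union for multi-part
#' units), used as the reference locations for residual variograms.
#'
#' @param units Units tibble from [area_units()].
#' @return Tibble with columns `id`, `partition`, `x`, `y`.
#' @export
unit_centroids <- function(units) {
  cents <- t(vapply(units$geometry, polygon_centroid, numeric(2L)))
  tibble::tibble(id = units$id, partition = units$partition,
                 x = cents[, 1L], y = cents[, 2L])
}

#' Build a regular quadrature grid over a set of areal units
#'
#' All areal covariances in the model are double integrals of the
#' exponential kernel over polygon pairs. They are approximated by averaging
#' the kernel over the points of a regular lattice (cell centres) that
#' covers the bounding box of all units; a point contributes to a unit when
#' it falls inside the unit's polygon. A point on a shared boundary is
#' assigned to exactly one unit per partition (first unit in row order
#' wins), so partitions stay disjoint.
#'
#' @param units Units tibble from [area_units()], containing one or both
#'   partitions.
#' @param spacing Grid spacing in metres.
#' @param quiet Suppress the per-partition minimum points-per-unit message.
#' @param on_empty What to do when the lattice misses a unit entirely:
#'   `"error"` (default) stops and names the unit, `"centroid"` supplements
#'   the lattice with one interior point per missed unit so that every
#'   unit keeps at least one quadrature node.
#' @return An object of class `quad_grid`: lattice points, spacing, the
#'   units, and per-partition point-to-unit assignments.
#' @examples
#' u <- area_units("A", "coarse", list(rect_ring(0, 1000, 0, 1000)))
#' g <- build_quadrature_grid(u, 500)
#' nrow(g$points)  # 4
#' @export
build_quadrature_grid <- function(units, spacing, quiet = FALSE,
                                  on_empty = c("error", "centroid")) {
  stopifnot(is.data.frame(units), nrow(units) > 0)
  on_empty <- match.arg(on_empty)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a single positive number (metres)", call. = FALSE)
  }
  bb <- units_bbox(units)
  xs <- seq(bb["xmin"] + spacing / 2, bb["xmax"], by = spacing)
  ys <- seq(bb["ymin"] + spacing / 2, bb["ymax"], by = spacing)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  if (nrow(pts) > 2e5) {
    stop("quadrature grid would have ", nrow(pts),
         " points; increase `spacing`", call. = FALSE)
  }

  parts <- intersect(c("coarse", "fine"), unique(units$partition))
  assign_part <- function(pts, p) {
    rows <- which(units$partition == p)
    idx <- rep(NA_integer_, nrow(pts))
    for (r in seq_along(rows)) {
      unassigned <- which(is.na(idx))
      if (!length(unassigned)) break
      inside <- points_in_polygon(pts[unassigned, , drop = FALSE],
                                  units$geometry[[rows[r]]])
      idx[unassigned[inside]] <- r
    }
    idx
  }
  part_index <- lapply(stats::setNames(parts, parts), assign_part, pts = pts)

  if (on_empty == "centroid") {
    extra <- NULL
    for (p in parts) {
      rows <- which(units$partition == p)
      counts <- tabulate(part_index[[p]], nbins = length(rows))
      for (r in which(counts == 0L)) {
        extra <- rbind(extra, interior_point(units$geometry[[rows[r]]], spacing))
      }
    }
    if (!is.null(extra)) {
      for (p in parts) part_index[[p]] <- c(part_index[[p]], assign_part(extra, p))
      pts <- rbind(pts, extra)
    }
  }

  for (p in parts) {
    rows <- which(units$partition == p)
    counts <- tabulate(part_index[[p]], nbins = length(rows))
    if (any(counts == 0L)) {
      bad <- units$id[rows][counts == 0L]
      stop("no quadrature points fall inside unit(s) ",
           paste(bad, collapse = ", "), " of the ", p,
           " partition; use a smaller `spacing` than ", spacing, " m",
           call. = FALSE)
    }
    if (any(counts < 4L) && !quiet) {
      message(sum(counts < 4L), " ", p, " unit(s) have fewer than 4 quadrature ",
              "points; areal integrals may be crude at spacing ", spacing, " m")
    }
    if (!quiet) {
      message("partition ", p, ": ", length(rows), " units, minimum ",
              min(counts), " points per unit")
    }
  }

  structure(
    list(points = pts, spacing = spacing, units = units,
         part_index = part_index, cache = new.env(parent = emptyenv())),
    class = "quad_grid"
  )
}

#' @export
print.quad_grid <- function(x, ...) {
  cat("<quad_grid> ", nrow(x$points), " points, spacing ", x$spacing, " m\n", sep = "")
  for (p in names(x$part_index)) {
    counts <- tabulate(x$part_index[[p]])
    cat("  ", p, ": ", length(counts), " units, points per unit ",
        min(counts), "-", max(counts), "\n", sep = "")
  }
  invisible(x)
}

grid_partition_units <- function(grid, partition) {
  grid$units[grid$units$partition == partition, , drop = FALSE]
}

grid_unit_points <- function(grid, partition, id) {
  idx <- grid$part_index[[partition]]
  if (is.null(idx)) stop("grid has no ", partition, " partition", call. = FALSE)
  u <- grid_partition_units(grid, partition)
  r <- match(id, u$id)
  if (is.na(r)) stop("unknown ", partition, " unit id: ", id, call. = FALSE)
  w <- which(idx == r)
  if (!length(w)) stop("unit ", id, " has no assigned quadrature points", call. = FALSE)
  grid$points[w, , drop = FALSE]
}

# Cached q x q inter-point distance matrix.
grid_dist <- function(grid) {
  if (is.null(grid$cache$D)) {
    if (nrow(grid$points) > 8000) {
      stop("dense distance matrix for ", nrow(grid$points),
           " quadrature points is too large; increase the grid spacing",
           call. = FALSE)
    }
    grid$cache$D <- pair_dist(grid$points, grid$points)
  }
  grid$cache$D
}

# Mean of exp(-d/delta) over all point pairs, aggregated by unit, for the
# partitions present in the grid. Returns within-partition matrices (cc, ff)
# and the coarse x fine cross matrix (cf). This is the quadrature
# approximation of the normalised double-integral factor f(A, B; delta) /
# (|A| |B|) shared by every areal covariance in the model.
kernel_factors <- function(grid, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a single positive number (metres)", call. = FALSE)
  }
  # memoize the last evaluation: prediction, residual and validation steps
  # all need the factors at the same fitted delta
  key <- sprintf("%.17g", delta)
  if (identical(grid$cache$exact_key, key)) return(grid$cache$exact_F)
  K <- exp(-grid_dist(grid) / delta)
  out <- list()
  idx <- lapply(grid$part_index, function(v) which(!is.na(v)))
  grp <- lapply(names(grid$part_index), function(p) {
    grid$part_index[[p]][idx[[p]]]
  })
  names(grp) <- names(grid$part_index)
  counts <- lapply(grp, tabulate)

  part_sum <- function(p) rowsum(K[idx[[p]], , drop = FALSE], grp[[p]])

  if (!is.null(grid$part_index$coarse)) {
    Sc <- part_sum("coarse")
    cc <- t(rowsum(t(Sc[, idx$coarse, drop = FALSE]), grp$coarse))
    out$cc <- cc / tcrossprod(counts$coarse)
    dimnames(out$cc) <- rep(list(grid_partition_units(grid, "coarse")$id), 2L)
  }
  if (!is.null(grid$part_index$fine)) {
    Sf <- part_sum("fine")
    ff <- t(rowsum(t(Sf[, idx$fine, drop = FALSE]), grp$fine))
    out$ff <- ff / tcrossprod(counts$fine)
    dimnames(out$ff) <- rep(list(grid_partition_units(grid, "fine")$id), 2L)
  }
  if (!is.null(out$cc) && !is.null(out$ff)) {
    cf <- t(rowsum(t(Sc[, idx$fine, drop = FALSE]), grp$fine))
    out$cf <- cf / outer(counts$coarse, counts$fine)
    dimnames(out$cf) <- list(grid_partition_units(grid, "coarse")$id,
                             grid_partition_units(grid, "fine")$id)
  }
  grid$cache$exact_key <- key
  grid$cache$exact_F <- out
  out
}

#' Normalised areal correlation factor between two units
#'
#' Quadrature approximation of the double integral of
#' `exp(-||x - x'|| / delta)` over the two polygons, divided by the product
#' of their areas: the mean of the kernel over all pairs of quadrature
#' points assigned to the two units. Symmetric in its unit arguments, lies
#' in (0, 1], and equals 1 only when both units collapse to the same single
#' point.
#'
#' @param grid A [build_quadrature_grid()] object.
#' @param id_a,id_b Unit ids.
#' @param delta Spatial correlation scale (metres).
#' @param partition_a,partition_b Partition of each unit.
#' @return A single number in (0, 1].
#' @export
areal_correlation_factor <- function(grid, id_a, id_b, delta,
                                     partition_a = "coarse",
                                     partition_b = partition_a) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  A <- grid_unit_points(grid, partition_a, id_a)
  B <- grid_unit_points(grid, partition_b, id_b)
  mean(exp(-pair_dist(A, B) / delta))
}

#' Areal covariance matrix of a partition
#'
#' Covariance matrix of the polygon-averaged Gaussian process over all
#' units of one partition: `tau2` times the normalised areal correlation
#' factor for every unit pair. Diagonal entries are at most `tau2` because
#' averaging over a polygon can only reduce the variance of the underlying
#' process.
#'
#' @param grid A [build_quadrature_grid()] object.
#' @param tau2 Process variance.
#' @param delta Spatial correlation scale (metres).
#' @param partition `"coarse"` or `"fine"`.
#' @return Symmetric matrix with unit ids as dimnames.
#' @export
areal_cov_matrix <- function(grid, tau2, delta, partition = "coarse") {
  if (!is.numeric(tau2) || tau2 <= 0) stop("`tau2` must be positive", call. = FALSE)
  F <- kernel_factors(grid, delta)
  key <- if (partition == "coarse") "cc" else "ff"
  if (is.null(F[[key]])) stop("grid has no ", partition, " partition", call. = FALSE)
  tau2 * F[[key]]
}

#' Covariance between the process at a point and a unit average
#'
#' `tau2` times the mean of `exp(-distance / delta)` from `x` to the
#' quadrature points of the unit; the area-normalised form, so the value is
#' the covariance between `U(x)` and the unit average of `U` and lies in
#' (0, `tau2`].
#'
#' @param x Numeric length-2 coordinate, or an n x 2 matrix of points.
#' @param grid A [build_quadrature_grid()] object.
#' @param id Unit id.
#' @param tau2,delta Kernel parameters.
#' @param partition Partition of the unit.
#' @return Numeric vector, one value per row of `x`.
#' @export
point_to_areal_cov <- function(x, grid, id, tau2, delta, partition = "coarse") {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  P <- grid_unit_points(grid, partition, id)
  tau2 * rowMeans(exp(-pair_dist(x, P) / delta))
}

# ---- histogram-accelerated kernel factors ------------------------------
# The optimizer needs kernel_factors() at hundreds of delta values. The
# pairwise point distances never change, so they are binned once per grid
# (bin width = spacing / 20, representative = the global mean distance in
# the bin); each new delta then costs one small matrix-vector product
# instead of a q x q exponential. The approximation error in any factor is
# below 1e-4 on the grids used here (checked by the test-suite against the
# exact path).
build_kernel_hist <- function(grid) {
  D <- grid_dist(grid)
  q <- nrow(D)
  w <- grid$spacing / 4
  nb <- as.integer(ceiling(max(D) / w)) + 1L
  # bin 1 holds the exact-zero self distances
  bin <- matrix(findInterval(D, seq(0, by = w, length.out = nb),
                             left.open = TRUE) + 1L, q, q)
  cnt_all <- tabulate(bin, nbins = nb)
  sum_all <- rep(0, nb)
  agg <- rowsum(c(D), c(bin))
  sum_all[as.integer(rownames(agg))] <- agg[, 1L]
  r <- ifelse(cnt_all > 0L, sum_all / cnt_all, 0)

  idx <- lapply(grid$part_index, function(v) which(!is.na(v)))
  grp <- lapply(names(grid$part_index), function(p) grid$part_index[[p]][idx[[p]]])
  names(grp) <- names(grid$part_index)

  # within-partition blocks are symmetric: ordered point pairs are pooled
  # into the unordered unit pair (a <= b)
  block_sym <- function(p) {
    ia <- idx[[p]]; ga <- grp[[p]]
    nA <- max(ga)
    gi <- rep(ga, times = length(ia)); gj <- rep(ga, each = length(ia))
    a <- pmin(gi, gj); b <- pmax(gi, gj)
    pid <- (a - 1L) * nA - ((a - 1L) * (a - 2L)) %/% 2L + b - a + 1L  # triangular index
    np <- (nA * (nA + 1L)) %/% 2L
    combined <- (pid - 1L) * nb + c(bin[ia, ia])
    C <- matrix(tabulate(combined, nbins = as.double(np) * nb), nb, np)
    list(C = C, n = nA, np = np)
  }
  block_cross <- function() {
    ia <- idx$coarse; ib <- idx$fine
    ga <- grp$coarse; gb <- grp$fine
    nA <- max(ga); nB <- max(gb)
    pid <- rep((ga - 1L) * nB, times = length(ib)) + rep(gb, each = length(ia))
    combined <- (pid - 1L) * nb + c(bin[ia, ib])
    C <- matrix(tabulate(combined, nbins = as.double(nA) * nB * nb), nb, nA * nB)
    list(C = C, nA = nA, nB = nB)
  }

  blocks <- list()
  if (!is.null(grp$coarse)) blocks$cc <- block_sym("coarse")
  if (!is.null(grp$fine)) blocks$ff <- block_sym("fine")
  if (!is.null(grp$coarse) && !is.null(grp$fine)) blocks$cf <- block_cross()

  # stack all blocks into one pair x bin count matrix for a single product,
  # and precompute the index maps that scatter the per-pair values back
  # into full (symmetric) matrices; the counts are sparse because any one
  # unit pair only spans a narrow band of distance bins
  C <- t(do.call(cbind, lapply(blocks, `[[`, "C")))
  if (length(C) > 8e7) {
    stop("kernel histogram would be too large; use a coarser grid", call. = FALSE)
  }
  totals <- rowSums(C)
  C <- Matrix::Matrix(C, sparse = TRUE)
  sizes <- vapply(blocks, function(b) ncol(b$C), 0L)
  offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offsets) <- names(sizes)
  tri_map <- function(n) {
    a <- pmin(row(diag(n)), col(diag(n))); b <- pmax(row(diag(n)), col(diag(n)))
    (a - 1L) * n - ((a - 1L) * (a - 2L)) %/% 2L + b - a + 1L
  }
  maps <- list()
  if (!is.null(blocks$cc)) {
    maps$cc <- matrix(offsets[["cc"]] + tri_map(blocks$cc$n), blocks$cc$n)
  }
  if (!is.null(blocks$ff)) {
    maps$ff <- matrix(offsets[["ff"]] + tri_map(blocks$ff$n), blocks$ff$n)
  }
  if (!is.null(blocks$cf)) {
    b <- blocks$cf  # pair id (a-1)*nB + bcol, row-major
    maps$cf <- matrix(offsets[["cf"]] +
                        rep(seq_len(b$nA) - 1L, times = b$nB) * b$nB +
                        rep(seq_len(b$nB), each = b$nA), b$nA, b$nB)
  }
  list(r = r, C = C, totals = totals, maps = maps,
       dims = lapply(blocks, function(b) if (!is.null(b$nA)) c(b$nA, b$nB) else c(b$n, b$n)))
}

# Same contract as kernel_factors(), via the precomputed histogram.
kernel_factors_fast <- function(grid, delta) {
  if (is.null(grid$cache$hist)) grid$cache$hist <- build_kernel_hist(grid)
  h <- grid$cache$hist
  vals <- as.numeric(h$C %*% exp(-h$r / delta)) / h$totals
  out <- lapply(h$maps, function(m) {
    M <- vals[m]
    dim(M) <- dim(m)
    M
  })
  if (!is.null(out$cc)) {
    dimnames(out$cc) <- rep(list(grid_partition_units(grid, "coarse")$id), 2L)
  }
  if (!is.null(out$ff)) {
    dimnames(out$ff) <- rep(list(grid_partition_units(grid, "fine")$id), 2L)
  }
  if (!is.null(out$cf)) {
    dimnames(out$cf) <- list(grid_partition_units(grid, "coarse")$id,
                             grid_partition_units(grid, "fine")$id)
  }
  out
}

# Mean kernel from arbitrary points to every unit of a partition:
# q x n_units matrix of mean exp(-d/delta).
point_unit_kernel <- function(pts, grid, delta, partition) {
  idx <- which(!is.na(grid$part_index[[partition]]))
  grp <- grid$part_index[[partition]][idx]
  K <- exp(-pair_dist(grid$points[idx, , drop = FALSE], as.matrix(pts)) / delta)
  S <- rowsum(K, grp)
  t(S / tabulate(grp))
}

#' Export a quadrature grid as CSV for audit
#'
#' Writes the lattice coordinates with their per-partition unit
#' assignments (`NA` where a point falls outside every unit).
#'
#' @param grid A [build_quadrature_grid()] object.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
export_grid <- function(grid, path) {
  out <- tibble::tibble(x = grid$points[, 1L], y = grid$points[, 2L])
  for (p in names(grid$part_index)) {
    u <- grid_partition_units(grid, p)
    out[[paste0(p, "_id")]] <- u$id[grid$part_index[[p]]]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
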