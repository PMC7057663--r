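#' Abridged life table
#'
#' Container for the abridged (Chiang) life-table quantities, assuming a
#' constant death probability within each age interval: per interval
#' `(a_{t-1}, a_t)`, the fraction `p_t` of the total population that has
#' not died in the interval, the fraction `d_t` that dies in it, and the
#' mean years `m_t` lived in the interval by those who die in it.
#'
#' @param age_breaks Strictly increasing vector of `T + 1` interval
#'   endpoints in years.
#' @param survive_frac `p_t`, length `T`, in \[0, 1\].
#' @param die_frac `d_t`, length `T`, in \[0, 1\].
#' @param mean_years_lived `m_t`, length `T`, non-negative years.
#' @return An object of class `life_table` (a tibble).
#' @seealso [chiang_leb()], [uk_abridged_breaks()]
#' @export
life_table <- function(age_breaks, survive_frac, die_frac, mean_years_lived) {
  if (length(age_breaks) < 2L || any(diff(age_breaks) <= 0)) {
    stop("`age_breaks` must be strictly increasing with at least 2 values",
         call. = FALSE)
  }
  T_ <- length(age_breaks) - 1L
  if (length(survive_frac) != T_ || length(die_frac) != T_ ||
      length(mean_years_lived) != T_) {
    stop("fractions must have length ", T_, " (one per age interval)", call. = FALSE)
  }
  bad <- survive_frac < 0 | survive_frac > 1 | die_frac < 0 | die_frac > 1 |
    survive_frac + die_frac > 1 + 1e-8
  if (any(bad)) {
    stop("inconsistent fractions in interval(s) ",
         paste(which(bad), collapse = ", "),
         ": p_t, d_t and p_t + d_t must lie in [0, 1]", call. = FALSE)
  }
  if (any(mean_years_lived < 0)) {
    stop("`mean_years_lived` must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    age_low = age_breaks[-length(age_breaks)], age_high = age_breaks[-1L],
    survive_frac = survive_frac, die_frac = die_frac,
    mean_years_lived = mean_years_lived
  )
  class(out) <- c("life_table", class(out))
  out
}

#' Standard UK abridged age breaks
#'
#' The 19-interval layout used for published LEB estimates: (0, 1),
#' (1, 4\] and five-year intervals up to 90.
#'
#' @return Numeric vector of 20 endpoints.
#' @export
uk_abridged_breaks <- function() c(0, 1, seq(5, 90, by = 5))

#' Life expectancy at birth (Chiang estimator)
#'
#' `LEB = sum_t [ (a_t - a_{t-1}) p_t + m_t d_t ]`: years lived by
#' survivors of each interval plus years lived by those dying within it.
#'
#' @param table A [life_table()].
#' @return Life expectancy at birth in years.
#' @examples
#' lt <- life_table(c(0, 10), survive_frac = 0, die_frac = 1,
#'                  mean_years_lived = 5)
#' chiang_leb(lt)  # 5
#' @export
chiang_leb <- function(table) {
  stopifnot(inherits(table, "life_table"))
  sum((table$age_high - table$age_low) * table$survive_frac +
        table$mean_years_lived * table$die_frac)
}

# ---- boundaries and tables ---------------------------------------------

#' Read areal-unit boundaries from GeoJSON
#'
#' Reads a FeatureCollection of Polygon / MultiPolygon features into a
#' units tibble. Coordinates must be in a projected planar CRS with metre
#' units; coordinates that look geographic (all within lon/lat bounds) are
#' rejected rather than silently reprojected. Interior rings (holes) are
#' not supported and raise an error.
#'
#' @param path GeoJSON file.
#' @param id_field Name of the feature property holding the unit id.
#' @param partition `"coarse"` or `"fine"`.
#' @return Units tibble (see [area_units()]).
#' @export
read_boundaries <- function(path, id_field, partition) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  if (!length(feats)) stop("no features in ", path, call. = FALSE)

  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  }
  poly_parts <- function(coords, what) {
    if (length(coords) > 1L) {
      stop("polygon with interior rings (holes) is not supported (feature ",
           what, ")", call. = FALSE)
    }
    list(ring_to_matrix(coords[[1L]]))
  }

  ids <- character(length(feats)); geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    idv <- f$properties[[id_field]]
    if (is.null(idv)) {
      stop("feature ", i, " has no property \"", id_field, "\"", call. = FALSE)
    }
    ids[i] <- as.character(idv)
    g <- f$geometry
    geoms[[i]] <- switch(
      g$type,
      Polygon = poly_parts(g$coordinates, ids[i]),
      MultiPolygon = do.call(c, lapply(g$coordinates, poly_parts, what = ids[i])),
      stop("unsupported geometry type ", g$type, " in feature ", ids[i],
           call. = FALSE)
    )
  }
  area_units(ids, partition, geoms)
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration naming the boundary files, data tables,
#' id fields, spacings, thresholds and seeds of an analysis run; see the
#' package vignette for the schema. Unknown fields are kept as-is.
#'
#' @param path YAML or JSON file.
#' @return A named list with a `config_hash` attribute.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(id_field = "id", quadrature_spacing = 150,
                   prediction_spacing = 250, seed = 1L, B = 1000L,
                   thresholds = c(79.2, 82.9))
  cfg <- utils::modifyList(defaults, cfg)
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

# Polynomial rolling hash over the deparsed configuration: a stable,
# dependency-free fingerprint recorded in run outputs (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load a misaligned dataset from files
#'
#' Reads both boundary files and both CSV tables named in a configuration
#' and joins them into a [misaligned_data()] object. Ids present on one
#' side but not the other are a hard error (the offending ids are named);
#' row order in the CSVs is irrelevant.
#'
#' The configuration needs: `coarse_boundaries`, `fine_boundaries`
#' (GeoJSON paths), `outcome_csv`, `covariate_csv`, and optionally
#' `id_field` (default `"id"`), `outcome_cols` (default `c("leb1",
#' "leb2")`), `covariate_col` (default `"imd"`).
#'
#' @param config A list (or path to a YAML/JSON file, see
#'   [read_run_config()]).
#' @return A list with elements `data` ([misaligned_data()]) and `units`.
#' @export
load_misaligned_data <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (f in c("coarse_boundaries", "fine_boundaries", "outcome_csv",
              "covariate_csv")) {
    if (is.null(config[[f]])) stop("config is missing `", f, "`", call. = FALSE)
    if (!file.exists(config[[f]])) stop("file not found: ", config[[f]], call. = FALSE)
  }
  id_field <- config$id_field %||% "id"
  units <- dplyr::bind_rows(
    read_boundaries(config$coarse_boundaries, id_field, "coarse"),
    read_boundaries(config$fine_boundaries, id_field, "fine")
  )
  outcome <- utils::read.csv(config$outcome_csv, check.names = FALSE)
  covariate <- utils::read.csv(config$covariate_csv, check.names = FALSE)
  data <- misaligned_data(
    units, outcome, covariate, id_col = id_field,
    outcome_cols = config$outcome_cols %||% c("leb1", "leb2"),
    covariate_col = config$covariate_col %||% "imd"
  )
  list(data = data, units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- surfaces -----------------------------------------------------------

#' Write a predictive field as gridded CSV
#'
#' One row per lattice point with predictive means and standard deviations
#' for both groups and, when thresholds are supplied, the non-exceedance
#' probabilities.
#'
#' @param field A [predictive_distribution()] result.
#' @param path Output CSV path.
#' @param thresholds Optional length-2 vector of thresholds (group 1,
#'   group 2) for NEP columns.
#' @return The exported tibble, invisibly.
#' @export
write_surface <- function(field, path, thresholds = NULL) {
  out <- tibble::tibble(
    x = field$points$x, y = field$points$y,
    mean1 = field$mean[, 1L], sd1 = field$sd[, 1L],
    mean2 = field$mean[, 2L], sd2 = field$sd[, 2L]
  )
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2L)
    out$nep1 <- nep(field, 1L, thresholds[1L])
    out$nep2 <- nep(field, 2L, thresholds[2L])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read back a gridded surface CSV
#'
#' @param path CSV written by [write_surface()].
#' @return A tibble.
#' @export
read_surface <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Iso-level contours of a predicted surface
#'
#' Contour lines of the predictive mean surface of one group at the given
#' outcome levels (years), computed on the regular lattice of the field.
#'
#' @param field A [predictive_distribution()] result on a regular lattice.
#' @param levels Outcome levels to contour.
#' @param group Outcome group.
#' @return Tibble with columns `level`, `piece`, `x`, `y`.
#' @export
surface_contours <- function(field, levels, group = 1L) {
  xs <- sort(unique(field$points$x)); ys <- sort(unique(field$points$y))
  z <- matrix(NA_real_, length(xs), length(ys))
  ix <- match(field$points$x, xs); iy <- match(field$points$y, ys)
  z[cbind(ix, iy)] <- field$mean[, group]
  cl <- grDevices::contourLines(xs, ys, z, levels = levels)
  if (!length(cl)) {
    return(tibble::tibble(level = numeric(0), piece = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  dplyr::bind_rows(lapply(seq_along(cl), function(i) {
    tibble::tibble(level = cl[[i]]$level, piece = i, x = cl[[i]]$x, y = cl[[i]]$y)
  }))
}
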