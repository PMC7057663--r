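#' Assemble a misaligned areal dataset
#'
#' Joins the per-unit outcome table (coarse partition) and covariate table
#' (fine partition) to their polygons. Row order is normalised to the unit
#' order of `units`; every unit must have exactly one data row and vice
#' versa. Missing values are an error.
#'
#' @param units Units tibble from [area_units()] holding both partitions.
#' @param outcome Data frame with a unit id column and two numeric outcome
#'   columns (group 1 then group 2, e.g. male and female life expectancy in
#'   years). Column names are matched case-insensitively against
#'   `outcome_cols`.
#' @param covariate Data frame with a unit id column and one numeric
#'   covariate column (e.g. a deprivation score).
#' @param id_col Name of the id column in both tables.
#' @param outcome_cols Names of the two outcome columns.
#' @param covariate_col Name of the covariate column.
#' @return An object of class `misaligned_data` with elements `units`,
#'   `outcome` (n x 2 matrix), `covariate` (length-m vector), `coarse_ids`,
#'   `fine_ids`.
#' @export
misaligned_data <- function(units, outcome, covariate, id_col = "id",
                            outcome_cols = c("leb1", "leb2"),
                            covariate_col = "imd") {
  stopifnot(is.data.frame(units), is.data.frame(outcome), is.data.frame(covariate))
  coarse <- units[units$partition == "coarse", , drop = FALSE]
  fine <- units[units$partition == "fine", , drop = FALSE]
  if (nrow(coarse) < 1L || nrow(fine) < 1L) {
    stop("`units` must contain both a coarse and a fine partition", call. = FALSE)
  }

  pick <- function(df, cols, what) {
    nm <- names(df)
    hit <- match(tolower(cols), tolower(nm))
    if (anyNA(hit)) {
      stop("column(s) ", paste(cols[is.na(hit)], collapse = ", "),
           " not found in the ", what, " table", call. = FALSE)
    }
    df[, nm[hit], drop = FALSE]
  }

  out_tab <- pick(outcome, c(id_col, outcome_cols), "outcome")
  cov_tab <- pick(covariate, c(id_col, covariate_col), "covariate")
  align <- function(tab, ids, what) {
    tab_ids <- as.character(tab[[1L]])
    if (anyDuplicated(tab_ids)) {
      stop("duplicated ids in the ", what, " table: ",
           paste(unique(tab_ids[duplicated(tab_ids)]), collapse = ", "),
           call. = FALSE)
    }
    extra <- setdiff(tab_ids, ids)
    missing <- setdiff(ids, tab_ids)
    if (length(extra)) {
      stop(what, " table has ids with no matching polygon: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (length(missing)) {
      stop("polygon(s) without a ", what, " row: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tab[match(ids, tab_ids), -1L, drop = FALSE]
  }

  y <- as.matrix(align(out_tab, coarse$id, "outcome"))
  v <- align(cov_tab, fine$id, "covariate")[[1L]]
  if (!is.numeric(y) || anyNA(y) || !is.numeric(v) || anyNA(v)) {
    stop("outcome and covariate values must be numeric with no missing values",
         call. = FALSE)
  }
  dimnames(y) <- list(coarse$id, outcome_cols)
  names(v) <- fine$id
  structure(
    list(units = units, outcome = y, covariate = v,
         coarse_ids = coarse$id, fine_ids = fine$id),
    class = "misaligned_data"
  )
}

#' @export
print.misaligned_data <- function(x, ...) {
  cat("<misaligned_data> ", length(x$coarse_ids), " coarse units (bivariate outcome), ",
      length(x$fine_ids), " fine units (covariate)\n", sep = "")
  invisible(x)
}

n_coarse <- function(data) length(data$coarse_ids)
n_fine <- function(data) length(data$fine_ids)

check_data_grid <- function(data, grid, min_units = 1L) {
  gc <- grid_partition_units(grid, "coarse")$id
  gf <- grid_partition_units(grid, "fine")$id
  if (!identical(gc, data$coarse_ids) || !identical(gf, data$fine_ids)) {
    stop("`grid` and `data` refer to different units (ids or order differ)",
         call. = FALSE)
  }
  if (nrow(data$outcome) < min_units || length(data$covariate) < min_units) {
    stop("at least ", min_units, " coarse and ", min_units,
         " fine units are required", call. = FALSE)
  }
  invisible(TRUE)
}
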