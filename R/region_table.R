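#' Construct a region-by-animal density table
#'
#' The universal input of the pipeline: a numeric matrix of non-negative
#' activity densities with one row per brain region and one column per animal.
#' Regional IEG expression density is correlated *across animals*, so the
#' cohort must contain at least 3 animals (the minimum group size at which a
#' correlation p-value is defined) and at least 2 regions.
#'
#' @param values numeric matrix, regions in rows and animals in columns. Row
#'   names are region labels (Allen-atlas-style abbreviations such as "BLA",
#'   "BMA", "PALv"); column names are animal IDs. Both are mandatory and must
#'   be unique.
#' @param check_nonnegative validate that all densities are `>= 0` (the
#'   default). Latent-scale synthetic tables (see [simulate_cohort()] with
#'   `transform = "none"`) may switch this off; Pearson correlation is
#'   location/scale invariant, so the sign of the values never affects the
#'   network.
#' @return a `region_table`: the validated matrix with class attribute set.
#' @examples
#' m <- matrix(abs(rnorm(12)), 3, 4,
#'             dimnames = list(c("BLA", "BMA", "PALv"), paste0("m", 1:4)))
#' region_table(m)
#' @export
region_table <- function(values, check_nonnegative = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (regions x animals)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry region row names and animal column names",
         call. = FALSE)
  }
  validate_region_table(values, check_nonnegative = check_nonnegative)
  structure(values, class = c("region_table", class(values)))
}

validate_region_table <- function(values, check_nonnegative = TRUE) {
  regions <- rownames(values)
  animals <- colnames(values)
  if (nrow(values) < 2L) {
    stop("need at least 2 regions, got ", nrow(values), call. = FALSE)
  }
  if (ncol(values) < 3L) {
    stop("need at least 3 animals for across-animal correlation, got ",
         ncol(values), call. = FALSE)
  }
  dup <- regions[duplicated(regions)]
  if (length(dup)) {
    stop("duplicate region label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- animals[duplicated(animals)]
  if (length(dup)) {
    stop("duplicate animal ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing or non-finite value at region '", regions[bad[1, 1]],
         "', animal '", animals[bad[1, 2]], "'", call. = FALSE)
  }
  if (check_nonnegative) {
    bad <- which(values < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("negative density at region '", regions[bad[1, 1]],
           "', animal '", animals[bad[1, 2]], "'", call. = FALSE)
    }
  }
  invisible(values)
}

#' @export
print.region_table <- function(x, ...) {
  cat("<region_table> ", nrow(x), " regions x ", ncol(x), " animals\n", sep = "")
  cat("regions: ", paste(utils::head(rownames(x), 6), collapse = ", "),
      if (nrow(x) > 6) ", ..." else "", "\n", sep = "")
  cat("animals: ", paste(utils::head(colnames(x), 6), collapse = ", "),
      if (ncol(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a region-by-animal table from CSV
#'
#' Expects the on-disk dialect written by [write_region_table()]: a UTF-8 CSV
#' whose first column (named `region`) holds region labels and whose remaining
#' columns hold one animal each, with a header row of animal IDs. Decimal
#' points, no thousands separators. Row and column order are preserved exactly
#' as on disk. Missing cells, negative values, duplicate labels or a cohort of
#' fewer than 3 animals are rejected with the offending cell or label named;
#' pairwise-complete correlation over missing entries is deliberately not
#' offered.
#'
#' @param path path to the CSV file.
#' @return a [region_table()].
#' @seealso [write_region_table()], [restrict_regions()]
#' @export
load_region_table <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (ncol(df) < 2L) {
    stop("table must have a region column plus at least one animal column",
         call. = FALSE)
  }
  regions <- as.character(df[[1]])
  animals <- colnames(df)[-1]
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      blank <- which(!nzchar(trimws(col)) | is.na(col))
      if (length(blank)) {
        stop("empty cell at region '", regions[blank[1]], "' (row ", blank[1],
             "), animal '", animals[j], "'", call. = FALSE)
      }
      col <- suppressWarnings(as.numeric(col))
    }
    nonnum <- which(is.na(col))
    if (length(nonnum)) {
      stop("missing or non-numeric cell at region '", regions[nonnum[1]],
           "' (row ", nonnum[1], "), animal '", animals[j], "'", call. = FALSE)
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(regions, animals)
  region_table(m)
}

#' Write a region-by-animal table to CSV
#'
#' Inverse of [load_region_table()]; a load -> write -> load cycle
#' round-trips bit-identically.
#'
#' @param table a [region_table()] (or matrix with dimnames).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path) {
  table <- as_region_table(table)
  df <- data.frame(region = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a table to a set of regions
#'
#' Subsets the node set, e.g. to a curated collection of reliably delineated
#' atlas regions. The returned rows follow the order of `keep`.
#'
#' @param table a [region_table()].
#' @param keep character vector of region labels to retain, all of which must
#'   be present in `table`.
#' @return a [region_table()] with `length(keep)` rows.
#' @export
restrict_regions <- function(table, keep) {
  table <- as_region_table(table)
  missing <- setdiff(keep, rownames(table))
  if (length(missing)) {
    stop("unknown region label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) < 2L) {
    stop("`keep` must retain at least 2 regions", call. = FALSE)
  }
  region_table(unclass(table)[keep, , drop = FALSE], check_nonnegative = FALSE)
}

as_region_table <- function(table) {
  if (inherits(table, "region_table")) return(table)
  region_table(table, check_nonnegative = FALSE)
}

#' Cavalieri point-count density
#'
#' Converts a raw regional label count into a density using a Cavalieri-style
#' area estimate: a mask of evenly spaced grid points (default spacing 22 um)
#' is overlaid on each section, the grid points falling inside the region are
#' summed, and the regional area is estimated as
#' `grid_points * spacing^2` (um^2). Density is `count / area` in labels per
#' um^2. All arguments are vectorized and recycled in the usual way.
#'
#' @param count non-negative integer count of IEG+ objects in the region.
#' @param grid_points non-negative integer count of grid points falling in the
#'   region, summed over sections. A region with `grid_points = 0` was never
#'   sampled and has no defined area, so it is an error — never silently 0 or
#'   infinite.
#' @param spacing grid spacing in micrometres (default 22).
#' @return density in labels per square micrometre.
#' @examples
#' cavalieri_density(10, 100)          # 10 / (100 * 22^2)
#' cavalieri_density(0, 50)            # 0
#' @export
cavalieri_density <- function(count, grid_points, spacing = 22) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("`count` must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(grid_points)) || any(grid_points < 0)) {
    stop("`grid_points` must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive", call. = FALSE)
  }
  if (any(grid_points == 0)) {
    stop("undefined area: grid_points is 0 for ", sum(grid_points == 0),
         " record(s); the region was absent from the sampled sections",
         call. = FALSE)
  }
  count / (grid_points * spacing^2)
}

#' Densities from paired count and grid-point tables
#'
#' Applies [cavalieri_density()] element-wise to a region-by-animal table of
#' raw label counts and a same-shaped table of grid-point counts.
#'
#' @param counts region-by-animal matrix (or `region_table`) of label counts.
#' @param grid_points matrix of grid-point counts with identical dimnames.
#' @param spacing grid spacing in micrometres (default 22).
#' @return a [region_table()] of densities in labels per um^2.
#' @export
density_from_counts <- function(counts, grid_points, spacing = 22) {
  if (!identical(dim(counts), dim(grid_points)) ||
      !identical(dimnames(counts), dimnames(grid_points))) {
    stop("`counts` and `grid_points` must have identical shape and dimnames",
         call. = FALSE)
  }
  dens <- cavalieri_density(unclass(counts), unclass(grid_points), spacing)
  region_table(matrix(dens, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts)))
}
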