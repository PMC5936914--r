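#' Filter occurrence data for duration/occupancy analysis
#'
#' Removes singletons (species known from exactly one locality, whose
#' durations and coverages would be dominated by preservation failure)
#' and species flagged extant (whose modern ranges are anthropogenically
#' constrained), and reports counts per exclusion reason.
#'
#' @param occ occurrence data.frame with columns `species`, `locality_id`,
#'   `extant` (logical).
#' @return list: `included` (character species vector), `excluded`
#'   (data.frame `species`, `reason`), `report` (named counts).
#' @export
filter_species <- function(occ) {
  stopifnot(all(c("species", "locality_id", "extant") %in% names(occ)))
  sp <- unique(occ$species)
  n_loc <- vapply(split(occ$locality_id, occ$species),
                  function(l) length(unique(l)), 0L)[sp]
  is_extant <- vapply(split(occ$extant, occ$species), any, TRUE)[sp]
  reason <- ifelse(is_extant, "extant",
                   ifelse(n_loc == 1L, "singleton", NA))
  excluded <- data.frame(species = sp[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  rownames(excluded) <- NULL
  list(included = sp[is.na(reason)], excluded = excluded,
       report = c(included = sum(is.na(reason)),
                  singleton = sum(reason == "singleton", na.rm = TRUE),
                  extant = sum(reason == "extant", na.rm = TRUE)))
}

#' Assign coordinates to half-degree grid cells
#'
#' Cells are half-open: a point on a cell boundary belongs to the cell
#' starting there. Cell indices are `floor(coordinate / cell_size)`.
#'
#' @param lat,lon coordinates in degrees (vectorized).
#' @param cell_size cell edge in degrees (default 0.5).
#' @return data.frame `cell_lat_index`, `cell_lon_index`, `cell_id`.
#' @export
assign_grid_cell <- function(lat, lon, cell_size = 0.5) {
  if (any(lat < -90 | lat > 90 | lon < -180 | lon > 180, na.rm = TRUE) ||
      anyNA(lat) || anyNA(lon)) {
    stop("invalid coordinates")
  }
  i <- floor(lat / cell_size)
  j <- floor(lon / cell_size)
  data.frame(cell_lat_index = as.integer(i), cell_lon_index = as.integer(j),
             cell_id = paste(i, j, sep = ":"))
}

#' Lower cell corners from grid indices
#'
#' @param cell_lat_index,cell_lon_index integer cell indices.
#' @param cell_size cell edge in degrees.
#' @return data.frame with the cell bounds.
#' @export
grid_cell_bounds <- function(cell_lat_index, cell_lon_index,
                             cell_size = 0.5) {
  data.frame(lat_min = cell_lat_index * cell_size,
             lat_max = (cell_lat_index + 1) * cell_size,
             lon_min = cell_lon_index * cell_size,
             lon_max = (cell_lon_index + 1) * cell_size)
}

# Assign each occurrence's age-interval midpoint to a time slice.
# Membership: young_ma <= mid < old_ma, except the oldest slice which is
# closed at its old boundary. Returns the slice name or NA.
assign_slice <- function(mid_age, slices) {
  out <- rep(NA_character_, length(mid_age))
  for (k in seq_len(nrow(slices))) {
    inb <- mid_age >= slices$young_ma[k] & mid_age < slices$old_ma[k]
    if (k == 1L) inb <- inb | mid_age == slices$old_ma[k]
    out[inb & is.na(out)] <- slices$slice[k]
  }
  out
}

#' Per-species, per-slice grid-cell occupancy
#'
#' For each time slice, occupancy of a species is the number of
#' half-degree cells holding at least one of its occurrences divided by
#' the number of cells holding at least one occurrence of any included
#' species in that slice. Occurrences are placed in slices by the
#' midpoint of their age interval. Slices in which the clade has no
#' occurrences yield no rows (occupancy undefined).
#'
#' @param occ occurrence data.frame (`species`, `lat`, `lon`, `max_age`,
#'   `min_age`).
#' @param slices slice table from [slice_table()].
#' @param species optional species subset (e.g. `filter_species()$included`).
#' @param cell_size cell edge in degrees.
#' @return data.frame `species`, `slice`, `n_cells`, `total_cells`,
#'   `occupancy`.
#' @export
occupancy_by_slice <- function(occ, slices, species = NULL,
                               cell_size = 0.5) {
  if (!nrow(slices)) stop("empty slice table")
  if (!is.null(species)) occ <- occ[occ$species %in% species, ]
  if (!nrow(occ)) {
    return(data.frame(species = character(0), slice = character(0),
                      n_cells = integer(0), total_cells = integer(0),
                      occupancy = numeric(0)))
  }
  mid <- (occ$max_age + occ$min_age) / 2
  sl <- assign_slice(mid, slices)
  cell <- assign_grid_cell(occ$lat, occ$lon, cell_size)$cell_id
  keep <- !is.na(sl)
  d <- data.frame(species = occ$species[keep], slice = sl[keep],
                  cell = cell[keep])
  out <- do.call(rbind, lapply(split(d, d$slice), function(ds) {
    total <- length(unique(ds$cell))
    per <- vapply(split(ds$cell, ds$species),
                  function(cl) length(unique(cl)), 0L)
    data.frame(species = names(per), slice = ds$slice[1],
               n_cells = as.integer(per), total_cells = total,
               occupancy = per / total)
  }))
  rownames(out) <- NULL
  out[order(out$species, match(out$slice, slices$slice)), ]
}

#' Maximum locality coverage per species
#'
#' The maximum over time slices of the per-slice occupancy, with ties
#' broken toward the older slice (first in slice order).
#'
#' @param occup output of [occupancy_by_slice()].
#' @param slices the slice table (defines old-to-young order).
#' @return data.frame `species`, `max_loc_cover`, `argmax_slice`.
#' @export
max_locality_coverage <- function(occup, slices) {
  if (!nrow(occup)) stop("species absent from all slices")
  out <- do.call(rbind, lapply(split(occup, occup$species), function(d) {
    d <- d[order(match(d$slice, slices$slice)), ]  # old -> young
    i <- which.max(d$occupancy)                    # first max = older slice
    data.frame(species = d$species[1], max_loc_cover = d$occupancy[i],
               argmax_slice = d$slice[i])
  }))
  rownames(out) <- NULL
  out
}
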