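#' Build the incidence cube
#'
#' Indexes a validated occurrence dataset into the structure all statistics
#' run on: the set of cells supporting each (epiphyte, host) pair, plus the
#' distinct label sets and the cell-to-area lookup.
#'
#' @param ds an `occurrence_dataset`.
#' @return An object of class `incidence_cube`: a list with `triples` (the
#'   unique epiphyte/host/cell data frame), `cell_to_area`, and sorted label
#'   vectors `lichens`, `hosts`, `cells`, `areas`.
#' @export
build_cube <- function(ds) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  r <- ds$records
  if (nrow(r) == 0) {
    stop_hostpref("cannot build a cube from an empty dataset",
                  class = "hostpref_validation_error")
  }
  new_cube(r[c("lichen_taxon", "host_taxon", "cell_id")],
           ds$cell_to_area[unique(r$cell_id)])
}

new_cube <- function(triples, cell_to_area) {
  rownames(triples) <- NULL
  structure(
    list(triples = triples,
         cell_to_area = cell_to_area,
         lichens = sort(unique(triples$lichen_taxon)),
         hosts = sort(unique(triples$host_taxon)),
         cells = sort(unique(triples$cell_id)),
         areas = sort(unique(unname(cell_to_area)))),
    class = "incidence_cube"
  )
}

#' Restrict a cube to a subset of cells
#'
#' Keeps only incidences recorded in the given cells; pairs left with no cell
#' disappear, and epiphyte/host sets are recomputed from what survives. Cell
#' ids not present in the cube are ignored with a warning. An empty selection
#' yields an empty cube (valid: all statistics on it are zero).
#'
#' @param cube an `incidence_cube`.
#' @param cells character vector of cell ids to keep.
#' @return An `incidence_cube` over the selected cells.
#' @export
restrict_cube <- function(cube, cells) {
  stopifnot(inherits(cube, "incidence_cube"))
  cells <- unique(as.character(cells))
  unknown <- setdiff(cells, cube$cells)
  if (length(unknown) > 0) {
    warning("ignoring ", length(unknown), " cell id(s) not present in cube")
    cells <- intersect(cells, cube$cells)
  }
  keep <- cube$triples$cell_id %in% cells
  triples <- cube$triples[keep, , drop = FALSE]
  new_cube(triples, cube$cell_to_area[intersect(names(cube$cell_to_area), cells)])
}

#' Restrict a cube to one geographic area
#'
#' @param cube an `incidence_cube`.
#' @param area an area id present in the cube.
#' @return An `incidence_cube` over that area's cells.
#' @export
restrict_area <- function(cube, area) {
  stopifnot(inherits(cube, "incidence_cube"))
  if (!area %in% cube$areas) {
    stop_hostpref("unknown area: ", area, class = "hostpref_lookup_error")
  }
  restrict_cube(cube, names(cube$cell_to_area)[cube$cell_to_area == area])
}

#' Cells supporting one epiphyte-host pair
#'
#' @param cube an `incidence_cube`.
#' @param lichen,host taxon labels.
#' @return character vector of cell ids (possibly empty), sorted.
#' @export
pair_cells <- function(cube, lichen, host) {
  t <- cube$triples
  sort(t$cell_id[t$lichen_taxon == lichen & t$host_taxon == host])
}

#' @export
print.incidence_cube <- function(x, ...) {
  cat("Incidence cube:", nrow(x$triples), "unique (epiphyte, host, cell) incidences\n")
  cat(sprintf("  %d epiphyte taxa, %d host taxa, %d cells, %d areas\n",
              length(x$lichens), length(x$hosts), length(x$cells),
              length(x$areas)))
  invisible(x)
}

# Integer-coded view of a cube used by the accumulation engine: for each
# (lichen, host) pair the indices of its cells, and for each lichen the
# indices of its pairs.
cube_index <- function(cube) {
  t <- cube$triples
  li <- match(t$lichen_taxon, cube$lichens)
  ci <- match(t$cell_id, cube$cells)
  pair_key <- paste(t$lichen_taxon, t$host_taxon, sep = "\r")
  pid <- match(pair_key, unique(pair_key))
  first <- !duplicated(pid)
  list(
    n_cells = length(cube$cells),
    n_lichens = length(cube$lichens),
    cells_by_pair = split(ci, pid),
    pairs_by_lichen = split(seq_len(max(pid)), li[first])
  )
}
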