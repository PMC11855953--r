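#' Host range of epiphyte taxa
#'
#' The host range of an epiphyte is the number of distinct host taxa it was
#' recorded on within the cube's scope. Epiphytes with host range 1 are the
#' "exclusive" (host-preferring) species the pipeline counts.
#'
#' @param cube an `incidence_cube`.
#' @param lichen optional single taxon label; if given, returns one count.
#' @return Named integer vector over all epiphytes, or a single integer.
#' @export
host_range <- function(cube, lichen = NULL) {
  stopifnot(inherits(cube, "incidence_cube"))
  pairs <- unique(cube$triples[c("lichen_taxon", "host_taxon")])
  ranges <- table(factor(pairs$lichen_taxon, levels = cube$lichens))
  ranges <- stats::setNames(as.integer(ranges), names(ranges))
  if (is.null(lichen)) return(ranges)
  if (!lichen %in% names(ranges)) {
    stop_hostpref("unknown epiphyte taxon: ", lichen,
                  class = "hostpref_lookup_error")
  }
  ranges[[lichen]]
}

#' Epiphytes exclusive to a single host
#'
#' Partitions the host-range-1 epiphytes by their (unique) host. Epiphytes
#' recorded on two or more hosts appear under no host.
#'
#' @param cube an `incidence_cube`.
#' @return Named list: host taxon -> sorted character vector of epiphytes
#'   found only on that host. Hosts with no exclusive species are omitted.
#' @export
exclusive_species <- function(cube) {
  stopifnot(inherits(cube, "incidence_cube"))
  pairs <- unique(cube$triples[c("lichen_taxon", "host_taxon")])
  rng <- host_range(cube)
  excl <- pairs[rng[pairs$lichen_taxon] == 1, , drop = FALSE]
  if (nrow(excl) == 0) return(stats::setNames(list(), character(0)))
  lapply(split(excl$lichen_taxon, excl$host_taxon), sort)
}

#' Number of host-exclusive epiphytes in a cube
#'
#' @param cube an `incidence_cube`.
#' @return Integer count of epiphytes with host range exactly 1.
#' @export
exclusivity_count <- function(cube) {
  stopifnot(inherits(cube, "incidence_cube"))
  sum(host_range(cube) == 1L)
}

#' Percentage of epiphytes exclusive to one host
#'
#' @param cube an `incidence_cube`.
#' @return `100 * exclusivity_count / number of epiphytes`, or `NA` for an
#'   empty cube.
#' @export
exclusivity_pct <- function(cube) {
  n <- length(cube$lichens)
  if (n == 0) return(NA_real_)
  100 * exclusivity_count(cube) / n
}

#' Per-host exclusivity table (regional scale)
#'
#' One row per host: cells where the host was recorded (`n_cells`), total
#' epiphyte species on the host (`tls`), species restricted to that host
#' within the whole cube (`rsps`), and the percentage `100 * rsps / tls`
#' rounded half-away-from-zero to one decimal. Rows are sorted by `rsps`
#' descending, ties alphabetical.
#'
#' @param cube an `incidence_cube`.
#' @param min_rsps keep only hosts with at least this many exclusive species
#'   (default 5, the conventional reporting threshold).
#' @return data frame with columns `host_taxon`, `n_cells`, `tls`, `rsps`,
#'   `rsps_pct`.
#' @export
host_table <- function(cube, min_rsps = 5) {
  stopifnot(inherits(cube, "incidence_cube"), min_rsps >= 0)
  t <- cube$triples
  n_cells <- vapply(split(t$cell_id, t$host_taxon),
                    function(x) length(unique(x)), 0L)
  tls <- vapply(split(t$lichen_taxon, t$host_taxon),
                function(x) length(unique(x)), 0L)
  excl <- exclusive_species(cube)
  rsps <- stats::setNames(integer(length(cube$hosts)), cube$hosts)
  rsps[names(excl)] <- lengths(excl)
  out <- data.frame(
    host_taxon = cube$hosts,
    n_cells = as.integer(n_cells[cube$hosts]),
    tls = as.integer(tls[cube$hosts]),
    rsps = as.integer(rsps[cube$hosts]),
    stringsAsFactors = FALSE
  )
  out$rsps_pct <- round_half_away(100 * out$rsps / out$tls, 1)
  out <- out[out$rsps >= min_rsps, , drop = FALSE]
  out <- out[order(-out$rsps, out$host_taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-area and pooled exclusivity table
#'
#' One row per geographic area with statistics computed on the cube
#' restricted to that area's cells, plus a pooled row over the full dataset
#' (labelled `"Total"`). Within an area, host range is evaluated from that
#' area's records alone, so a species exclusive locally counts even if it
#' uses other hosts elsewhere; the pooled row uses the whole cube.
#'
#' @param ds an `occurrence_dataset`.
#' @return data frame with columns `area_id`, `n_cells`, `n_hosts`, `tls`,
#'   `rsps`, `rsps_pct` (one decimal); last row is the pooled total.
#' @export
area_table <- function(ds) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  cube <- build_cube(ds)
  row_for <- function(c, label) {
    data.frame(
      area_id = label,
      n_cells = length(c$cells),
      n_hosts = length(c$hosts),
      tls = length(c$lichens),
      rsps = exclusivity_count(c),
      rsps_pct = round_half_away(exclusivity_pct(c), 1),
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(cube$areas, function(a) row_for(restrict_area(cube, a), a))
  out <- rbind(do.call(rbind, rows), row_for(cube, "Total"))
  rownames(out) <- NULL
  out
}

#' Rank hosts by number of occupied cells
#'
#' @param ds an `occurrence_dataset` (or an `incidence_cube`).
#' @return data frame `host_taxon`, `n_cells`, sorted descending; ties broken
#'   alphabetically.
#' @export
rank_hosts_by_cells <- function(ds) {
  cube <- if (inherits(ds, "incidence_cube")) ds else build_cube(ds)
  t <- cube$triples
  n_cells <- vapply(split(t$cell_id, t$host_taxon),
                    function(x) length(unique(x)), 0L)
  out <- data.frame(host_taxon = names(n_cells),
                    n_cells = as.integer(n_cells),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cells, out$host_taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank epiphytes by host range
#'
#' @param cube an `incidence_cube`.
#' @return data frame `lichen_taxon`, `host_range`, sorted descending; ties
#'   broken alphabetically.
#' @export
rank_lichens_by_host_range <- function(cube) {
  rng <- host_range(cube)
  out <- data.frame(lichen_taxon = names(rng),
                    host_range = as.integer(rng),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$host_range, out$lichen_taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
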