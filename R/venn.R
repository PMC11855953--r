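#' Partition a focal host's epiphyte flora across areas
#'
#' For every epiphyte recorded on the focal host within the listed areas,
#' its membership class is the exact set of areas where an (epiphyte, focal
#' host) record exists. Classes are the regions of a Venn diagram over the
#' areas; they are pairwise disjoint and together cover the focal host's
#' epiphyte species in those areas. Exclusivity here is relative to the focal
#' host and the listed areas only — a species in a single-area class may
#' still occur on other hosts anywhere.
#'
#' @param ds an `occurrence_dataset`.
#' @param focal_host host taxon label; must be recorded in at least one of
#'   the listed areas.
#' @param areas character vector of area ids (default: all areas in the
#'   dataset, sorted). At most 10 (2^n - 1 classes are enumerated).
#' @return A `venn_partition`: list with `focal_host`, `areas` and `classes`,
#'   a named list over all non-empty area subsets (names are area ids joined
#'   by `"&"`, in the order of `areas`), each a sorted character vector of
#'   epiphyte taxa (possibly empty).
#' @export
venn_partition <- function(ds, focal_host, areas = NULL) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  r <- ds$records
  if (is.null(areas)) areas <- sort(unique(r$area_id))
  areas <- as.character(areas)
  unknown <- setdiff(areas, unique(r$area_id))
  if (length(unknown) > 0) {
    stop_hostpref("unknown area(s): ", paste(unknown, collapse = ", "),
                  class = "hostpref_lookup_error")
  }
  if (length(areas) > 10) {
    stop_hostpref("refusing to enumerate classes for more than 10 areas",
                  class = "hostpref_argument_error")
  }
  on_host <- r[r$host_taxon == focal_host & r$area_id %in% areas,
               c("lichen_taxon", "area_id")]
  if (nrow(on_host) == 0) {
    stop_hostpref("host '", focal_host, "' has no records in the listed areas",
                  class = "hostpref_lookup_error")
  }
  membership <- lapply(split(on_host$area_id, on_host$lichen_taxon), unique)

  subset_key <- function(members) {
    paste(areas[areas %in% members], collapse = "&")
  }
  classes <- list()
  n <- length(areas)
  for (bits in seq_len(2^n - 1)) {
    sub <- areas[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0]
    classes[[paste(sub, collapse = "&")]] <- character(0)
  }
  keys <- vapply(membership, subset_key, "")
  for (sp in names(membership)) {
    k <- keys[[sp]]
    classes[[k]] <- c(classes[[k]], sp)
  }
  classes <- lapply(classes, sort)
  structure(list(focal_host = focal_host, areas = areas, classes = classes),
            class = "venn_partition")
}

#' Per-area exclusive counts from a Venn partition
#'
#' Sizes of the singleton membership classes: species recorded on the focal
#' host in exactly one of the listed areas.
#'
#' @param vp a `venn_partition`.
#' @return Named integer vector over the partition's areas.
#' @export
area_exclusive_counts <- function(vp) {
  stopifnot(inherits(vp, "venn_partition"))
  stats::setNames(
    vapply(vp$areas, function(a) length(vp$classes[[a]]), 0L),
    vp$areas
  )
}

#' Tabulate a Venn partition
#'
#' @param x a `venn_partition`.
#' @param row.names,optional,... ignored (data frame method signature).
#' @return data frame with `membership_class`, `count`, `species_list`
#'   (taxa joined by `";"`).
#' @export
as.data.frame.venn_partition <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    membership_class = names(x$classes),
    count = lengths(x$classes),
    species_list = vapply(x$classes, paste, "", collapse = ";"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  total <- sum(lengths(x$classes))
  cat(sprintf("Venn partition of epiphytes on '%s' over %d areas (%s)\n",
              x$focal_host, length(x$areas), paste(x$areas, collapse = ", ")))
  cat(sprintf("  %d species in %d non-empty classes\n", total,
              sum(lengths(x$classes) > 0)))
  excl <- area_exclusive_counts(x)
  cat("  single-area exclusives:",
      paste(sprintf("%s=%d", names(excl), excl), collapse = ", "), "\n")
  invisible(x)
}
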