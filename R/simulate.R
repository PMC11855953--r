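#' Configuration for the occurrence simulator
#'
#' Defaults emulate the shape of a large regional epiphyte survey: hundreds
#' of epiphyte taxa on tens of woody hosts over a few hundred 10 km grid
#' cells split into six geographic areas, with a quarter of the epiphytes
#' true single-host specialists, generalist niche breadths following a
#' truncated geometric law whose tail reaches ranges of ~40-50 hosts, and
#' strongly heterogeneous host occupancy (the commonest host occupying just
#' under half the cells).
#'
#' @param n_lichens number of epiphyte taxa (default 700).
#' @param n_hosts number of host taxa (default 70).
#' @param n_cells number of grid cells (default 480).
#' @param n_areas number of geographic areas; cells are split into
#'   contiguous, as-even-as-possible blocks (default 6).
#' @param p_specialist probability an epiphyte's true niche is a single host
#'   (default 0.25).
#' @param breadth_prob success probability of the truncated geometric law on
#'   {2, ..., n_hosts} governing generalist niche breadth (default 0.1:
#'   most generalists use few hosts, the tail reaches ~40-50).
#' @param occupancy_range range from which each host's per-cell occupancy
#'   probability is drawn uniformly (default c(0.01, 0.45)).
#' @param p_detect probability an epiphyte is recorded in a cell where one
#'   of its niche hosts is present, independent per (epiphyte, host, cell)
#'   (default 0.3).
#' @param seed integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_lichens = 700, n_hosts = 70, n_cells = 480,
                       n_areas = 6, p_specialist = 0.25, breadth_prob = 0.1,
                       occupancy_range = c(0.01, 0.45), p_detect = 0.3,
                       seed = 1) {
  cfg <- list(n_lichens = as.integer(n_lichens), n_hosts = as.integer(n_hosts),
              n_cells = as.integer(n_cells), n_areas = as.integer(n_areas),
              p_specialist = p_specialist, breadth_prob = breadth_prob,
              occupancy_range = as.numeric(occupancy_range),
              p_detect = p_detect, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_lichens >= 1, n_hosts >= 1, n_cells >= 1,
              n_areas >= 1, n_areas <= n_cells,
              p_specialist >= 0, p_specialist <= 1,
              breadth_prob > 0, breadth_prob <= 1,
              length(occupancy_range) == 2,
              occupancy_range[1] > 0, occupancy_range[2] <= 1,
              occupancy_range[1] <= occupancy_range[2],
              p_detect >= 0, p_detect <= 1)
  })
  structure(cfg, class = "sim_config")
}

# Truncated geometric draw on {2..max_k}: P(k) proportional to
# (1 - prob)^(k - 2). Degenerates to the point mass at 2 when max_k == 2.
rtrunc_geom <- function(n, prob, max_k) {
  if (max_k <= 2) return(rep(2L, n))
  support <- 2:max_k
  w <- (1 - prob)^(support - 2)
  sample(support, n, replace = TRUE, prob = w)
}

#' Simulate an occurrence dataset with known truth
#'
#' Generates hosts with heterogeneous cell occupancy, epiphytes with true
#' host niches (single-host specialists with probability `p_specialist`,
#' otherwise truncated-geometric generalists), and presence records by
#' independent per-(epiphyte, host, cell) detection where a niche host is
#' present. The realized truth is returned alongside the dataset so recovery
#' of the specialist fraction can be checked. Hosts that draw an empty cell
#' set are redrawn within the seeded stream (up to 100 times, then an
#' error), so every host occupies at least one cell.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_result`: list with `dataset` (an `occurrence_dataset`,
#'   possibly lacking undetected taxa) and `truth` (list with `niche`,
#'   `host_cells`, `specialist`, `cell_area`, `config`).
#' @export
simulate_occurrences <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lichens <- sprintf("L%04d", seq_len(cfg$n_lichens))
  hosts <- sprintf("H%03d", seq_len(cfg$n_hosts))
  cells <- sprintf("C%04d", seq_len(cfg$n_cells))
  areas <- sprintf("A%d", seq_len(cfg$n_areas))
  # contiguous, as-even-as-possible blocks of cells per area
  cell_area <- stats::setNames(
    areas[rep(seq_len(cfg$n_areas),
              times = diff(round(seq(0, cfg$n_cells,
                                     length.out = cfg$n_areas + 1))))],
    cells)

  with_seed(cfg$seed, {
    occ_prob <- stats::runif(cfg$n_hosts, cfg$occupancy_range[1],
                             cfg$occupancy_range[2])
    host_cells <- vector("list", cfg$n_hosts)
    names(host_cells) <- hosts
    for (h in seq_len(cfg$n_hosts)) {
      for (try in seq_len(100)) {
        present <- stats::rbinom(cfg$n_cells, 1, occ_prob[h]) == 1
        if (any(present)) break
      }
      if (!any(present)) {
        stop_hostpref("host ", hosts[h], " occupied no cell after 100 draws",
                      class = "hostpref_simulation_error")
      }
      host_cells[[h]] <- cells[present]
    }

    specialist <- stats::runif(cfg$n_lichens) < cfg$p_specialist
    breadth <- ifelse(specialist, 1L,
                      rtrunc_geom(cfg$n_lichens, cfg$breadth_prob,
                                  cfg$n_hosts))
    niche <- lapply(seq_len(cfg$n_lichens), function(i) {
      sort(sample(hosts, breadth[i]))
    })
    names(niche) <- lichens

    # one candidate row per (epiphyte, niche host, occupied cell); keep each
    # with probability p_detect, independently
    pair_lichen <- rep(lichens, lengths(niche))
    pair_host <- unlist(niche, use.names = FALSE)
    n_per_pair <- lengths(host_cells)[pair_host]
    cand_cell <- unlist(host_cells[pair_host], use.names = FALSE)
    hit <- stats::runif(length(cand_cell)) < cfg$p_detect
    records <- data.frame(
      lichen_taxon = rep(pair_lichen, n_per_pair)[hit],
      host_taxon = rep(pair_host, n_per_pair)[hit],
      cell_id = cand_cell[hit],
      stringsAsFactors = FALSE
    )
    if (nrow(records) == 0) {
      stop_hostpref("simulation produced no records (p_detect too low?)",
                    class = "hostpref_simulation_error")
    }
    records$area_id <- unname(cell_area[records$cell_id])

    structure(
      list(dataset = occurrence_dataset(records),
           truth = list(niche = niche, host_cells = host_cells,
                        specialist = specialist, cell_area = cell_area,
                        config = cfg)),
      class = "sim_result"
    )
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated occurrence data (seed", x$truth$config$seed, ")\n")
  print(x$dataset)
  cat(sprintf("  true specialist fraction: %.3f\n", mean(x$truth$specialist)))
  invisible(x)
}

#' Specialist-fraction recovery under subsampling
#'
#' Compares the realized specialist fraction (share of detected epiphytes
#' whose true niche is one host) with the apparent exclusivity percentage
#' observed at random cell subsamples of increasing size. Under incomplete
#' sampling the apparent exclusivity overestimates the true specialist
#' fraction — generalists masquerade as specialists until enough cells
#' reveal their other hosts.
#'
#' @param sim a `sim_result` from [simulate_occurrences()].
#' @param fracs fractions of cells to subsample (default c(0.1, 0.25, 0.5, 1)).
#' @param n_rep random subsamples per fraction (default 20).
#' @param seed seed for the subsampling.
#' @return data frame with `frac`, `n_cells`, `apparent_excl_pct` (mean over
#'   replicates); attributes `true_specialist_pct` (among detected taxa) and
#'   `apparent_full_pct`.
#' @export
recovery_report <- function(sim, fracs = c(0.1, 0.25, 0.5, 1), n_rep = 20,
                            seed = 1) {
  stopifnot(inherits(sim, "sim_result"))
  cube <- build_cube(sim$dataset)
  n <- length(cube$cells)
  detected <- cube$lichens
  true_pct <- 100 * mean(lengths(sim$truth$niche[detected]) == 1)
  full_pct <- exclusivity_pct(cube)

  rows <- with_seed(seed, {
    lapply(fracs, function(f) {
      k <- max(1L, round(f * n))
      pcts <- vapply(seq_len(n_rep), function(r) {
        sub <- restrict_cube(cube, sample(cube$cells, k))
        p <- exclusivity_pct(sub)
        if (is.na(p)) 0 else p
      }, 0)
      data.frame(frac = f, n_cells = k, apparent_excl_pct = mean(pcts))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "true_specialist_pct") <- true_pct
  attr(out, "apparent_full_pct") <- full_pct
  out
}
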