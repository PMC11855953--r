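# Shared fixtures and independent brute-force oracles. The oracles work
# directly on the raw record data frame with naive loops, never through the
# cube machinery they are used to check.

toy_t1_df <- function() {
  data.frame(
    lichen_taxon = c("L1", "L1", "L2", "L2", "L3"),
    host_taxon   = c("H1", "H2", "H1", "H1", "H2"),
    cell_id      = c("U1", "U2", "U1", "U3", "U3"),
    area_id      = c("A",  "A",  "A",  "B",  "B"),
    stringsAsFactors = FALSE
  )
}

toy_t1 <- function() occurrence_dataset(toy_t1_df())

write_toy_csv <- function(path, extra_rows = NULL) {
  df <- rbind(toy_t1_df(), extra_rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Random small dataset; reproducible given seed. Defaults give cubes with at
# most 6 recorded cells, suitable for exhaustive enumeration.
random_dataset <- function(seed, n_cells = NULL, n_lichens = NULL,
                           n_hosts = NULL, n_areas = 2) {
  set.seed(seed)
  n_cells <- if (is.null(n_cells)) sample(2:6, 1) else n_cells
  n_lichens <- if (is.null(n_lichens)) sample(3:8, 1) else n_lichens
  n_hosts <- if (is.null(n_hosts)) sample(2:4, 1) else n_hosts
  cells <- sprintf("U%02d", seq_len(n_cells))
  areas <- sprintf("AR%d", seq_len(n_areas))
  cell_area <- setNames(sample(areas, n_cells, replace = TRUE), cells)
  rows <- list()
  for (i in seq_len(n_lichens)) {
    hosts_i <- sample(sprintf("H%02d", seq_len(n_hosts)),
                      sample.int(min(3, n_hosts), 1))
    for (h in hosts_i) {
      cs <- sample(cells, sample.int(min(3, n_cells), 1))
      rows[[length(rows) + 1]] <- data.frame(
        lichen_taxon = sprintf("L%02d", i), host_taxon = h,
        cell_id = cs, area_id = unname(cell_area[cs]),
        stringsAsFactors = FALSE)
    }
  }
  occurrence_dataset(do.call(rbind, rows))
}

with_seed_for_tests <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Brute-force host ranges from raw records.
oracle_host_ranges <- function(records) {
  out <- integer(0)
  for (l in unique(records$lichen_taxon)) {
    out[l] <- length(unique(records$host_taxon[records$lichen_taxon == l]))
  }
  out
}

# Brute-force exclusivity count on records, optionally restricted to cells.
oracle_exclusivity <- function(records, cells = NULL) {
  if (!is.null(cells)) {
    records <- records[records$cell_id %in% cells, , drop = FALSE]
  }
  if (nrow(records) == 0) return(0L)
  sum(oracle_host_ranges(records) == 1L)
}
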