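test_that("reading deduplicates and counts distinct labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path, extra_rows = toy_t1_df()[1, ])  # one exact duplicate
  ds <- read_occurrences(path)
  expect_s3_class(ds, "occurrence_dataset")
  expect_equal(nrow(ds$records), 5)
  expect_equal(ds$duplicates_dropped, 1)
  v <- validation_report(ds)
  expect_equal(v[c("n_lichens", "n_hosts", "n_cells", "n_areas")],
               list(n_lichens = 3, n_hosts = 2, n_cells = 3, n_areas = 2))
})

test_that("dialects and column remapping are honoured", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- toy_t1_df()
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_occurrences(tsv)$records, toy_t1()$records)

  renamed <- withr::local_tempfile(fileext = ".csv")
  names(df) <- c("species", "tree", "utm", "zone")
  write.csv(df, renamed, row.names = FALSE, quote = FALSE)
  ds <- read_occurrences(renamed, col_map = c(
    lichen_taxon = "species", host_taxon = "tree",
    cell_id = "utm", area_id = "zone"))
  expect_equal(ds$records, toy_t1()$records)
})

test_that("validation errors name the offending column, row or cell", {
  df <- toy_t1_df()
  expect_error(occurrence_dataset(df[, -2]), "host_taxon",
               class = "hostpref_format_error")
  df_bad <- df; df_bad$cell_id[3] <- "  "
  expect_error(occurrence_dataset(df_bad), "row",
               class = "hostpref_validation_error")
  df_area <- df; df_area$area_id[df_area$cell_id == "U1"][1] <- "B"
  expect_error(occurrence_dataset(df_area), "U1",
               class = "hostpref_consistency_error")
})

test_that("labels are trimmed and internal whitespace collapsed", {
  df <- toy_t1_df()
  df$lichen_taxon[1] <- "  L1 "
  df$host_taxon[1] <- "H1"
  ds <- occurrence_dataset(df)
  expect_equal(sort(unique(ds$records$lichen_taxon)), c("L1", "L2", "L3"))
  df2 <- data.frame(lichen_taxon = "Usnea   substerilis", host_taxon = "H1",
                    cell_id = "U1", area_id = "A")
  expect_equal(occurrence_dataset(df2)$records$lichen_taxon,
               "Usnea substerilis")
})

test_that("write -> read round-trips label-for-label", {
  for (seed in 1:5) {
    ds <- random_dataset(seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_occurrences(ds, path)
    back <- read_occurrences(path)
    expect_equal(back$records[order(back$records$lichen_taxon,
                                    back$records$host_taxon,
                                    back$records$cell_id), ],
                 ds$records[order(ds$records$lichen_taxon,
                                  ds$records$host_taxon,
                                  ds$records$cell_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("the cube indexes pair-to-cell incidences exactly", {
  cube <- build_cube(toy_t1())
  expect_equal(pair_cells(cube, "L1", "H1"), "U1")
  expect_equal(pair_cells(cube, "L1", "H2"), "U2")
  expect_equal(pair_cells(cube, "L2", "H1"), c("U1", "U3"))
  expect_equal(pair_cells(cube, "L3", "H2"), "U3")
  expect_equal(pair_cells(cube, "L3", "H1"), character(0))
  expect_setequal(cube$lichens, c("L1", "L2", "L3"))
  expect_setequal(cube$areas, c("A", "B"))
  # total incidence mass equals the number of deduplicated records
  expect_equal(nrow(cube$triples), nrow(toy_t1()$records))
  expect_error(build_cube(structure(list(records = toy_t1_df()[0, ]),
                                    class = "occurrence_dataset")),
               class = "hostpref_validation_error")
})

test_that("restriction commutes with construction and is idempotent", {
  for (seed in 1:8) {
    ds <- random_dataset(seed)
    cube <- build_cube(ds)
    keep <- sample(cube$cells, max(1, length(cube$cells) %/% 2))
    a <- restrict_cube(cube, keep)
    # filter records first, then build
    recs <- ds$records[ds$records$cell_id %in% keep, , drop = FALSE]
    b <- build_cube(occurrence_dataset(recs))
    expect_equal(a$triples[order(a$triples$lichen_taxon, a$triples$host_taxon,
                                 a$triples$cell_id), ],
                 b$triples[order(b$triples$lichen_taxon, b$triples$host_taxon,
                                 b$triples$cell_id), ],
                 ignore_attr = TRUE)
    expect_equal(restrict_cube(a, keep), a)            # idempotent
    expect_equal(restrict_cube(cube, cube$cells), cube) # identity
  }
})

test_that("degenerate restrictions behave as documented", {
  cube <- build_cube(toy_t1())
  empty <- restrict_cube(cube, character(0))
  expect_length(empty$lichens, 0)
  expect_length(empty$hosts, 0)
  expect_equal(exclusivity_count(empty), 0)
  expect_true(is.na(exclusivity_pct(empty)))
  expect_warning(r <- restrict_cube(cube, c("U1", "NOPE")), "not present")
  expect_equal(r$cells, "U1")
})
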