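test_that("trajectories reproduce the hand-enumerated toy values", {
  cube <- build_cube(toy_t1())
  expect_equal(exclusivity_trajectory(cube, c("U1", "U2", "U3")), c(2L, 1L, 2L))
  expect_equal(exclusivity_trajectory(cube, c("U3", "U2", "U1")), c(2L, 3L, 2L))
  one <- restrict_cube(cube, "U1")
  expect_equal(exclusivity_trajectory(one, "U1"), exclusivity_count(one))
  expect_error(exclusivity_trajectory(cube, c("U1", "U2")),
               class = "hostpref_argument_error")
  expect_error(exclusivity_trajectory(cube, c("U1", "U1", "U2")),
               class = "hostpref_argument_error")
})

test_that("the fast engine matches per-step recomputation exactly", {
  for (seed in 1:10) {
    ds <- random_dataset(seed)
    cube <- build_cube(ds)
    set.seed(seed + 1000)
    for (r in 1:3) {
      ord <- sample(cube$cells)
      expect_identical(exclusivity_trajectory(cube, ord),
                       exclusivity_trajectory(cube, ord, engine = "reference"))
    }
  }
})

test_that("exhaustive enumeration reproduces the toy curve exactly", {
  cube <- build_cube(toy_t1())
  ex <- exhaustive_curve(cube)
  expect_equal(ex$n_perm, 6)
  expect_equal(ex$steps$mean, c(10 / 6, 14 / 6, 2))
  expect_equal(ex$steps$min, c(1, 1, 2))
  expect_equal(ex$steps$max, c(2, 3, 2))
  expect_error(exhaustive_curve(cube, max_cells = 2),
               class = "hostpref_argument_error")
})

test_that("duplicated cells flatten the exhaustive mean curve", {
  # two cells with identical records: both orders give the same trajectory
  ds <- occurrence_dataset(data.frame(
    lichen_taxon = c("L1", "L1"), host_taxon = c("H1", "H1"),
    cell_id = c("U1", "U2"), area_id = "A"))
  ex <- exhaustive_curve(build_cube(ds))
  expect_equal(ex$steps$mean, c(1, 1))
  expect_equal(ex$steps$min, ex$steps$max)
})

test_that("sampled curves are reproducible and close at the last step", {
  for (seed in c(3, 8)) {
    cube <- build_cube(random_dataset(seed))
    c1 <- accumulation_curve(cube, n_perm = 25, seed = 99)
    c2 <- accumulation_curve(cube, n_perm = 25, seed = 99)
    expect_identical(c1$steps, c2$steps)
    n <- nrow(c1$steps)
    full <- exclusivity_count(cube)
    expect_equal(c1$steps$min[n], full)
    expect_equal(c1$steps$max[n], full)
    expect_true(all(c1$steps$min <= c1$steps$mean))
    expect_true(all(c1$steps$mean <= c1$steps$max))
  }
  expect_error(accumulation_curve(build_cube(toy_t1()), n_perm = 0),
               class = "hostpref_argument_error")
})

test_that("every permutation's trajectory ends at the full-cube count", {
  for (seed in 1:6) {
    cube <- build_cube(random_dataset(seed))
    cv <- accumulation_curve(cube, n_perm = 40, seed = seed, keep = TRUE)
    endpoint <- cv$trajectories[nrow(cv$trajectories), ]
    expect_true(all(endpoint == exclusivity_count(cube)))
  }
})

test_that("all-specialist exclusivity accumulation equals vegan's exact richness accumulation", {
  # when every epiphyte uses exactly one host, the exclusivity count reduces
  # to species richness, for which specaccum(method = "exact") gives the
  # analytic mean over all incorporation orders
  set.seed(42)
  for (rep in 1:3) {
    n_cells <- sample(3:5, 1)
    cells <- sprintf("U%d", seq_len(n_cells))
    rows <- do.call(rbind, lapply(1:6, function(i) {
      cs <- sample(cells, sample.int(n_cells, 1))
      data.frame(lichen_taxon = sprintf("L%d", i),
                 host_taxon = sprintf("H%d", i),  # private host: specialist
                 cell_id = cs, area_id = "A", stringsAsFactors = FALSE)
    }))
    cube <- build_cube(occurrence_dataset(rows))
    m <- table(cube$triples$cell_id, cube$triples$lichen_taxon)
    m <- unclass(pmin(m, 1))
    # specaccum warns about zero variance at the final site; harmless here
    sac <- suppressWarnings(
      vegan::specaccum(as.data.frame.matrix(m), method = "exact"))
    ex <- exhaustive_curve(cube)
    expect_equal(ex$steps$mean, as.numeric(sac$richness), tolerance = 1e-10)
  }
})

test_that("per-area curves use stable scope-specific seeds", {
  ds <- toy_t1()
  curves <- curves_per_area(ds, n_perm = 10, seed = 5)
  expect_named(curves, c("A", "B", "regional"))
  expect_equal(nrow(curves$A$steps), 2)
  expect_equal(nrow(curves$B$steps), 1)
  expect_equal(nrow(curves$regional$steps), 3)
  expect_equal(curves$regional$steps$mean[3], 2)
  # identical master seed -> identical curves
  again <- curves_per_area(ds, n_perm = 10, seed = 5)
  expect_identical(lapply(curves, `[[`, "steps"), lapply(again, `[[`, "steps"))
  # adding a new area must not perturb existing areas' curves
  extra <- rbind(toy_t1_df(), data.frame(
    lichen_taxon = "L9", host_taxon = "H9", cell_id = "U9", area_id = "C"))
  with_c <- curves_per_area(occurrence_dataset(extra), n_perm = 10, seed = 5)
  expect_identical(with_c$A$steps, curves$A$steps)
  expect_identical(with_c$B$steps, curves$B$steps)
})
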