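#' Exclusivity along one cell-incorporation order
#'
#' Recomputes the host-exclusivity count on the cube restricted to the first
#' k cells of `order`, for k = 1..n. The default engine tracks, per epiphyte,
#' the steps at which its first and second host become visible (the species
#' counts as exclusive from the first until just before the second); the
#' `"reference"` engine recomputes every step from scratch and exists as the
#' slow, obviously-correct mirror the fast path is tested against.
#'
#' @param cube an `incidence_cube`.
#' @param order character vector: a permutation of `cube$cells`.
#' @param engine `"fast"` (default) or `"reference"`.
#' @return Integer vector of length `length(cube$cells)`.
#' @export
exclusivity_trajectory <- function(cube, order, engine = c("fast", "reference")) {
  stopifnot(inherits(cube, "incidence_cube"))
  engine <- match.arg(engine)
  order <- as.character(order)
  if (length(order) != length(cube$cells) ||
      !setequal(order, cube$cells) || anyDuplicated(order) > 0) {
    stop_hostpref("`order` must be a permutation of the cube's cells",
                  class = "hostpref_argument_error")
  }
  if (engine == "reference") {
    return(vapply(seq_along(order), function(k) {
      exclusivity_count(restrict_cube(cube, order[seq_len(k)]))
    }, 0L))
  }
  idx <- cube_index(cube)
  traj_from_index(idx, match(order, cube$cells))
}

# Fast trajectory on a prebuilt cube_index. `order_idx` holds cell indices in
# incorporation order. A pair activates at the first step including one of
# its cells; an epiphyte is exclusive from its first pair activation up to
# (not including) its second.
traj_from_index <- function(idx, order_idx) {
  n <- idx$n_cells
  pos <- integer(n)
  pos[order_idx] <- seq_len(n)
  act <- vapply(idx$cells_by_pair, function(ix) min(pos[ix]), 0L)
  n1 <- n + 1L
  bounds <- vapply(idx$pairs_by_lichen, function(p) {
    a <- act[p]
    if (length(a) == 1L) return(c(a, n1))
    m1 <- which.min(a)
    c(a[m1], min(a[-m1]))
  }, integer(2))
  delta <- tabulate(bounds[1L, ], nbins = n1) -
    tabulate(pmin(bounds[2L, ], n1), nbins = n1)
  cumsum(delta)[seq_len(n)]
}

new_accumulation_curve <- function(scope, steps, n_perm, seed = NA_integer_,
                                   exhaustive = FALSE) {
  structure(
    list(scope = scope, n_cells = nrow(steps), n_perm = n_perm, seed = seed,
         exhaustive = exhaustive, steps = steps),
    class = "accumulation_curve"
  )
}

#' Host-preference accumulation curve
#'
#' Draws `n_perm` uniform random permutations of the cube's cells, computes
#' the exclusivity trajectory of each, and summarises per step with the
#' arithmetic mean and the min/max envelope. Every trajectory ends at the
#' same point — the full cube's exclusivity count — so the envelope closes at
#' the last step. The mean need not be monotone: an added cell can reveal a
#' second host for a previously exclusive species.
#'
#' @param cube an `incidence_cube` with at least one cell.
#' @param n_perm number of random incorporation orders (default 99).
#' @param seed integer seed; the curve is reproducible given (`cube`,
#'   `n_perm`, `seed`). Orders are drawn independently, so duplicate orders
#'   can occur, as in standard accumulation-curve practice.
#' @param scope label stored on the curve (an area id or `"regional"`).
#' @param keep if `TRUE`, store the full step-by-permutation trajectory
#'   matrix on the curve as `$trajectories` (useful for diagnostics).
#' @return An `accumulation_curve`: list with `scope`, `n_cells`, `n_perm`,
#'   `seed` and `steps`, a data frame `step`, `mean`, `min`, `max`.
#' @export
accumulation_curve <- function(cube, n_perm = 99, seed = 1,
                               scope = "regional", keep = FALSE) {
  stopifnot(inherits(cube, "incidence_cube"))
  if (n_perm < 1) {
    stop_hostpref("n_perm must be >= 1", class = "hostpref_argument_error")
  }
  n <- length(cube$cells)
  if (n == 0) {
    stop_hostpref("cube has no cells", class = "hostpref_argument_error")
  }
  idx <- cube_index(cube)
  trajs <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) traj_from_index(idx, sample.int(n)),
           integer(n))
  })
  trajs <- matrix(trajs, nrow = n)
  steps <- data.frame(
    step = seq_len(n),
    mean = rowMeans(trajs),
    min = apply(trajs, 1, min),
    max = apply(trajs, 1, max)
  )
  curve <- new_accumulation_curve(scope, steps, as.integer(n_perm),
                                  as.integer(seed))
  if (keep) curve$trajectories <- trajs
  curve
}

#' Exact accumulation curve by full enumeration
#'
#' Enumerates all `n!` incorporation orders and returns the exact per-step
#' mean and extremes. Exponential cost, so it refuses cubes with more than
#' `max_cells` cells; it exists as the exact oracle the sampled curve is
#' validated against.
#'
#' @param cube an `incidence_cube`.
#' @param max_cells enumeration guard (default 8).
#' @param scope label stored on the curve.
#' @return An `accumulation_curve` with `n_perm = factorial(n_cells)`.
#' @export
exhaustive_curve <- function(cube, max_cells = 8, scope = "regional") {
  stopifnot(inherits(cube, "incidence_cube"))
  n <- length(cube$cells)
  if (n == 0) {
    stop_hostpref("cube has no cells", class = "hostpref_argument_error")
  }
  if (n > max_cells) {
    stop_hostpref("refusing exhaustive enumeration of ", n,
                  " cells (limit ", max_cells, ")",
                  class = "hostpref_argument_error")
  }
  perms <- all_permutations(n)
  trajs <- vapply(perms, function(ord) {
    exclusivity_trajectory(cube, cube$cells[ord], engine = "reference")
  }, integer(n))
  trajs <- matrix(trajs, nrow = n)
  steps <- data.frame(
    step = seq_len(n),
    mean = rowMeans(trajs),
    min = apply(trajs, 1, min),
    max = apply(trajs, 1, max)
  )
  new_accumulation_curve(scope, steps, ncol(trajs), exhaustive = TRUE)
}

# All permutations of 1..n as a list of integer vectors (n! of them).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in sub) {
      i <- i + 1L
      out[[i]] <- c(k, rest[p])
    }
  }
  out
}

#' Accumulation curves per area plus the regional curve
#'
#' Runs [accumulation_curve()] on each area's restriction of the dataset and
#' on the full (regional) cube. Per-area seeds are derived from the master
#' seed and a stable hash of the area label, so adding or dropping an area
#' leaves the other areas' curves unchanged.
#'
#' @param ds an `occurrence_dataset`.
#' @param n_perm permutations per curve (default 99).
#' @param seed master seed.
#' @return Named list of `accumulation_curve`s: one per area (by area id)
#'   plus `"regional"`.
#' @export
curves_per_area <- function(ds, n_perm = 99, seed = 1) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  cube <- build_cube(ds)
  out <- list()
  for (a in cube$areas) {
    sub <- restrict_area(cube, a)
    if (length(sub$cells) == 0) {
      warning("area ", a, " has no cells; skipped")
      next
    }
    out[[a]] <- accumulation_curve(sub, n_perm = n_perm,
                                   seed = area_seed(seed, a), scope = a)
  }
  out[["regional"]] <- accumulation_curve(cube, n_perm = n_perm,
                                          seed = area_seed(seed, "regional"),
                                          scope = "regional")
  out
}

area_seed <- function(master, label) {
  as.integer((as.numeric(master) + stable_hash(label)) %% 2147483647)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  kind <- if (isTRUE(x$exhaustive)) "exhaustive" else "sampled"
  cat(sprintf("Accumulation curve [%s], scope '%s': %d cells, %d orders\n",
              kind, x$scope, x$n_cells, x$n_perm))
  cat(sprintf("  final exclusivity count: %g\n",
              x$steps$mean[x$n_cells]))
  invisible(x)
}

#' Plot an accumulation curve
#'
#' Mean exclusivity as a solid black line with the min/max envelope as
#' dashed red lines, against the number of incorporated cells.
#'
#' @param x an `accumulation_curve`.
#' @param ... passed to [plot()].
#' @export
plot.accumulation_curve <- function(x, ...) {
  s <- x$steps
  plot(s$step, s$mean, type = "l", col = "black", lwd = 2,
       ylim = range(s$min, s$max),
       xlab = "Number of cells", ylab = "Exclusive epiphyte species",
       main = sprintf("Host-preference accumulation (%s)", x$scope), ...)
  graphics::lines(s$step, s$min, col = "red", lty = 2)
  graphics::lines(s$step, s$max, col = "red", lty = 2)
  invisible(x)
}
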