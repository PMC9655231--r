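#' Default planted hotspot shapes
#'
#' The ground-truth mask of the synthetic benchmark scenario: four
#' disjoint, mutually non-adjacent connected patches of deliberately
#' different shapes, totalling 279 cells on the default 30 x 40 grid —
#' a quasi-circular blob (101 cells), an elongated irregular snake (36),
#' a concave C-shaped polygon (84), and a compact blob with a slender
#' L-shaped tail (58). Patches keep a Chebyshev distance of at least 2
#' cells from each other, so they stay separate even under queen
#' contiguity. The layout is deterministic and anchored to the top-left
#' of the grid, so larger grids simply gain background cells.
#'
#' @param nrows,ncols Grid dimensions; at least 30 x 40.
#' @return A tibble with columns `row`, `col` (0-based), `shape` (one of
#'   `"blob"`, `"snake"`, `"cring"`, `"tailed"`) and `unit_id` (row-major
#'   id on the `nrows` x `ncols` grid).
#' @examples
#' nrow(default_shapes())  # 279
#' @export
default_shapes <- function(nrows = 30, ncols = 40) {
  if (nrows < 30 || ncols < 40) {
    stop("the default hotspot layout needs a grid of at least 30 x 40 cells",
         call. = FALSE)
  }
  disk <- function(r0, c0, rad2) {
    g <- expand.grid(row = 0:29, col = 0:39)
    g[(g$row - r0)^2 + (g$col - c0)^2 <= rad2, ]
  }
  blob <- disk(8, 8, 32)

  snake_row <- c(2, 2, 3, 3, 4, 5, 5, 6, 7, 7, 8, 8, 9, 10, 10, 11, 12, 12)
  snake <- data.frame(
    row = rep(snake_row, each = 2) + c(0L, 1L),
    col = rep(19 + seq_along(snake_row), each = 2)
  )

  cring <- expand.grid(row = 16:25, col = 3:14)
  cring <- cring[!(cring$row %in% 19:22 & cring$col %in% 6:14), ]

  tailed <- rbind(
    disk(21, 30, 13),
    data.frame(row = 21, col = 34:39),
    data.frame(row = 22:28, col = 39)
  )

  out <- rbind(
    cbind(blob, shape = "blob"),
    cbind(snake, shape = "snake"),
    cbind(cring, shape = "cring"),
    cbind(tailed, shape = "tailed")
  )
  out <- tibble::as_tibble(out)
  out$unit_id <- as.integer(out$row * ncols + out$col + 1L)
  out[order(out$unit_id), c("row", "col", "shape", "unit_id")]
}

#' Generate a synthetic hotspot scenario
#'
#' Plants high-valued hotspots on a Poisson noise background. Background
#' cells draw i.i.d. counts from `Poisson(lam)`; cells in the truth mask
#' draw from the upper tail of the same distribution — `Poisson(lam)`
#' conditioned on being at least the `(1 - tail_q)` quantile (for the
#' defaults `lam = 3`, `tail_q = 0.05` the threshold is 6, so every
#' hotspot cell holds at least 6 cases). Sampling uses exact inverse-CDF
#' truncation, so results are fully reproducible under a seed.
#'
#' @param nrows,ncols Grid dimensions (default 30 x 40).
#' @param lam Poisson mean of the background counts (default 3).
#' @param tail_q Upper-tail probability defining hotspot values (default
#'   0.05, i.e. the top 5 percent).
#' @param truth Ground-truth hotspot cells: a tibble with `unit_id` (such
#'   as [default_shapes()], the default) or an integer vector of unit ids.
#' @param cell_size Cell side length (default 1, so areas are in cells).
#' @param seed Optional integer seed.
#' @return A `grid_lattice` tibble with a `value` column; the planted mask
#'   is kept in `attr(, "truth")` (integer unit ids) and the scenario
#'   parameters in `attr(, "scenario")`.
#' @export
generate_counts <- function(nrows = 30, ncols = 40, lam = 3, tail_q = 0.05,
                            truth = NULL, cell_size = 1, seed = NULL) {
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  if (tail_q <= 0 || tail_q >= 1) stop("`tail_q` must be in (0, 1)", call. = FALSE)
  if (is.null(truth)) truth <- default_shapes(nrows, ncols)
  truth_ids <- if (is.data.frame(truth)) truth$unit_id else as.integer(truth)
  n <- nrows * ncols
  if (length(truth_ids) && (min(truth_ids) < 1L || max(truth_ids) > n)) {
    stop("truth mask falls outside the grid", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- build_regular_grid(nrows, ncols, cell_size)
  value <- stats::rpois(n, lam)
  if (length(truth_ids)) {
    q <- stats::qpois(1 - tail_q, lam)
    lo <- stats::ppois(q - 1, lam)
    u <- stats::runif(length(truth_ids), lo, 1)
    value[truth_ids] <- stats::qpois(u, lam)  # truncated Poisson, value >= q
  }
  g$value <- as.numeric(value)
  attr(g, "truth") <- sort(unique(truth_ids))
  attr(g, "scenario") <- list(nrows = nrows, ncols = ncols, lam = lam,
                              tail_q = tail_q, seed = seed)
  g
}

#' Benchmark detectors on synthetic replicates
#'
#' Repeats the synthetic scenario, runs each requested detector at the
#' given significance level, and evaluates every detection against the
#' planted truth. Replicate seeds derive from the master seed by a
#' counter (`seed + replicate - 1`) and are recorded in the output.
#'
#' @param methods Detectors to compare, a subset of `"scan"`, `"gstar"`,
#'   `"moran"`, `"amoeba"`.
#' @param n_replicates Number of independent synthetic fields (default 20).
#' @param nrows,ncols,lam,tail_q,truth Scenario parameters, passed to
#'   [generate_counts()].
#' @param alpha Significance level for every detector (default 0.05).
#' @param n_sim Monte Carlo permutations for the scan and AMOEBA nulls
#'   (default 99; the local statistics use their analytic z-tests).
#' @param seed Master seed.
#' @return A tibble of class `hotspot_benchmark`: one row per replicate
#'   and method with the full [evaluate()] indicator set. [tidy()] on the
#'   result gives per-method means and standard deviations.
#' @export
run_benchmark <- function(methods = c("scan", "gstar", "moran", "amoeba"),
                          n_replicates = 20, nrows = 30, ncols = 40,
                          lam = 3, tail_q = 0.05, truth = NULL,
                          alpha = 0.05, n_sim = 99, seed = NULL) {
  bad <- setdiff(methods, c("scan", "gstar", "moran", "amoeba"))
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_replicates < 1) {
    out <- tibble::tibble(replicate = integer(), method = character(),
                          seed = integer())
    class(out) <- unique(c("hotspot_benchmark", class(out)))
    return(out)
  }
  seed <- seed %||% 1L
  rows <- list()
  for (r in seq_len(n_replicates)) {
    seed_r <- as.integer(seed) + r - 1L
    g <- generate_counts(nrows, ncols, lam, tail_q, truth = truth,
                         seed = seed_r)
    tru <- attr(g, "truth")
    for (m in methods) {
      det <- detect_hotspots(g, method = m, alpha = alpha, n_sim = n_sim,
                             seed = seed_r)
      ev <- evaluate(det, truth = tru)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(replicate = r, method = m, seed = seed_r), ev
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("hotspot_benchmark", class(out)))
  out
}
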