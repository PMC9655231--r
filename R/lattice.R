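#' Build a regular grid lattice
#'
#' Constructs the spatial data model used throughout hotgrid: a rectangular
#' lattice of square cells in row-major order. Cell `(r, c)` (0-based) has its
#' centroid at `((c + 0.5) * cell_size, (r + 0.5) * cell_size)`, so the grid
#' lives in the first quadrant with the origin at the top-left cell corner.
#'
#' @param nrows,ncols Number of rows and columns (positive integers).
#' @param cell_size Side length of each square cell, in an arbitrary but
#'   consistent planar length unit. Areas are `cell_size^2`.
#'
#' @return A tibble of class `grid_lattice` with one row per cell, columns
#'   `unit_id` (1-based, row-major), `row`, `col` (0-based indices), `x`, `y`
#'   (centroid coordinates) and `area`. Lattice-level metadata (dimensions,
#'   cell size, total area) is stored in the `"lattice"` attribute and can be
#'   read with [lattice_info()].
#'
#' @examples
#' g <- build_regular_grid(3, 4)
#' lattice_info(g)$total_area
#' @export
build_regular_grid <- function(nrows, ncols, cell_size = 1) {
  if (length(nrows) != 1L || length(ncols) != 1L ||
      !is.finite(nrows) || !is.finite(ncols) ||
      nrows < 1 || ncols < 1 || nrows != floor(nrows) || ncols != floor(ncols)) {
    stop("`nrows` and `ncols` must be positive integers", call. = FALSE)
  }
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive length", call. = FALSE)
  }
  nrows <- as.integer(nrows)
  ncols <- as.integer(ncols)
  n <- nrows * ncols
  row <- rep(seq_len(nrows) - 1L, each = ncols)
  col <- rep(seq_len(ncols) - 1L, times = nrows)
  out <- tibble::tibble(
    unit_id = seq_len(n),
    row = row,
    col = col,
    x = (col + 0.5) * cell_size,
    y = (row + 0.5) * cell_size,
    area = rep(cell_size^2, n)
  )
  new_grid_lattice(out, list(
    type = "grid", nrows = nrows, ncols = ncols,
    cell_size = cell_size, total_area = n * cell_size^2
  ))
}

new_grid_lattice <- function(tbl, info) {
  attr(tbl, "lattice") <- info
  class(tbl) <- unique(c("grid_lattice", class(tbl)))
  tbl
}

#' Lattice metadata
#'
#' @param lattice A `grid_lattice` tibble.
#' @return A list with at least `type` (`"grid"` or `"polygon"`) and
#'   `total_area`; regular grids also carry `nrows`, `ncols` and `cell_size`.
#' @export
lattice_info <- function(lattice) {
  info <- attr(lattice, "lattice", exact = TRUE)
  if (is.null(info)) {
    # tolerate plain tibbles that still have the grid columns
    if (all(c("row", "col", "area") %in% names(lattice))) {
      cs <- sqrt(lattice$area[1])
      info <- list(
        type = "grid",
        nrows = max(lattice$row) + 1L,
        ncols = max(lattice$col) + 1L,
        cell_size = cs,
        total_area = sum(lattice$area)
      )
    } else {
      stop("not a hotgrid lattice: missing \"lattice\" attribute", call. = FALSE)
    }
  }
  info
}

is_grid <- function(lattice) identical(lattice_info(lattice)$type, "grid")

#' Contiguity and distance-band spatial weights
#'
#' Builds the binary spatial weights used by the local statistics. On a
#' regular grid, `rook` links the 4 edge-sharing neighbours and `queen` the 8
#' surrounding cells; `distance` links units whose centroid distance is at
#' most `threshold`. On polygon lattices, rook means a shared boundary
#' segment and queen additionally admits shared corner points.
#'
#' @param lattice A `grid_lattice` tibble.
#' @param rule One of `"queen"` (default, the convention used by all
#'   detectors here), `"rook"` or `"distance"`.
#' @param threshold Centroid distance band, required iff `rule = "distance"`.
#' @param include_self Should each unit be its own neighbour (`w_ii = 1`)?
#'   The Getis-Ord G* statistic requires `TRUE`; local Moran's I requires
#'   `FALSE`.
#' @return An object of class `hotgrid_weights`: a list with `neighbors`
#'   (a list of sorted neighbour ids per unit, including the unit itself
#'   when `include_self`), `rule`, `threshold`, `include_self` and `n`.
#' @examples
#' w <- contiguity_weights(build_regular_grid(3, 3), "queen")
#' lengths(w$neighbors)
#' @export
contiguity_weights <- function(lattice, rule = c("queen", "rook", "distance"),
                               threshold = NULL, include_self = FALSE) {
  rule <- match.arg(rule)
  n <- nrow(lattice)
  if (rule == "distance") {
    if (is.null(threshold) || !is.finite(threshold) || threshold <= 0) {
      stop("`threshold` (a positive distance) is required for rule = \"distance\"",
           call. = FALSE)
    }
    nbrs <- distance_neighbors(lattice$x, lattice$y, threshold)
  } else if (is_grid(lattice)) {
    nbrs <- grid_neighbors(lattice$row, lattice$col,
                           lattice_info(lattice)$nrows,
                           lattice_info(lattice)$ncols,
                           queen = rule == "queen")
  } else {
    nbrs <- polygon_neighbors(attr(lattice, "geometry"), queen = rule == "queen")
  }
  if (include_self) {
    nbrs <- lapply(seq_len(n), function(i) sort(c(i, nbrs[[i]])))
  }
  structure(
    list(neighbors = nbrs, rule = rule,
         threshold = if (rule == "distance") threshold else NULL,
         include_self = include_self, n = n),
    class = "hotgrid_weights"
  )
}

# queen/rook neighbours by index arithmetic; ids exclude self
grid_neighbors <- function(row, col, nrows, ncols, queen) {
  offsets <- if (queen) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  n <- length(row)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    rr <- row[i] + offsets[, "dr"]
    cc <- col[i] + offsets[, "dc"]
    ok <- rr >= 0 & rr < nrows & cc >= 0 & cc < ncols
    nbrs[[i]] <- sort(as.integer(rr[ok] * ncols + cc[ok] + 1L))
  }
  nbrs
}

distance_neighbors <- function(x, y, threshold) {
  n <- length(x)
  nbrs <- vector("list", n)
  thr2 <- threshold^2 * (1 + 1e-12)  # tolerate fp noise at the band edge
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    ids <- which(d2 <= thr2)
    nbrs[[i]] <- ids[ids != i]
  }
  nbrs
}

# polygon contiguity from ring coordinates: queen = any shared vertex,
# rook = a shared edge (two consecutive shared vertices)
polygon_neighbors <- function(geometry, queen) {
  n <- length(geometry)
  vkey <- lapply(geometry, function(m) {
    m <- m[-nrow(m), , drop = FALSE]  # drop closing vertex
    paste(signif(m[, 1], 12), signif(m[, 2], 12))
  })
  ekey <- lapply(geometry, function(m) {
    k <- paste(signif(m[, 1], 12), signif(m[, 2], 12))
    a <- k[-length(k)]; b <- k[-1]
    paste(pmin(a, b), pmax(a, b))
  })
  key <- if (queen) vkey else ekey
  lookup <- split(rep(seq_len(n), lengths(key)), unlist(key))
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- unique(unlist(lookup[key[[i]]], use.names = FALSE))
    nbrs[[i]] <- sort(cand[cand != i])
  }
  nbrs
}

#' Perimeter of a patch of lattice units
#'
#' Total exposed boundary length of a set of units: cell edges (or polygon
#' boundary segments) not shared with another member. Interior holes count
#' toward the perimeter, and the perimeter of a union of disjoint,
#' non-adjacent patches is the sum of the patch perimeters.
#'
#' @param lattice A `grid_lattice` tibble.
#' @param members Unit ids (integer) forming the patch; must be nonempty.
#' @return The boundary length, in the lattice's length unit.
#' @examples
#' patch_perimeter(build_regular_grid(4, 4), c(1, 2, 5, 6))  # 2x2 block -> 8
#' @export
patch_perimeter <- function(lattice, members) {
  members <- unique(as.integer(members))
  if (length(members) == 0L) {
    stop("`members` must be a nonempty set of unit ids", call. = FALSE)
  }
  if (any(members < 1L | members > nrow(lattice))) {
    stop("`members` contains unit ids outside the lattice", call. = FALSE)
  }
  if (is_grid(lattice)) {
    info <- lattice_info(lattice)
    inset <- logical(nrow(lattice))
    inset[members] <- TRUE
    row <- lattice$row[members]
    col <- lattice$col[members]
    exposed <- 0L
    for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- row + off[1]; cc <- col + off[2]
      inside <- rr >= 0L & rr < info$nrows & cc >= 0L & cc < info$ncols
      nb_id <- rr * info$ncols + cc + 1L
      shared <- inside & inset[pmax(nb_id, 1L)]
      exposed <- exposed + sum(!shared)
    }
    exposed * info$cell_size
  } else {
    geometry <- attr(lattice, "geometry")
    ek <- lapply(members, function(i) {
      m <- geometry[[i]]
      k <- paste(signif(m[, 1], 12), signif(m[, 2], 12))
      a <- k[-length(k)]; b <- k[-1]
      len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
      tibble::tibble(key = paste(pmin(a, b), pmax(a, b)), len = len)
    })
    edges <- dplyr::bind_rows(ek)
    tab <- table(edges$key)
    sum(edges$len[edges$key %in% names(tab)[tab == 1L]])
  }
}

#' Connected components of a unit set
#'
#' Groups a set of units into contiguous patches under the given rule.
#'
#' @param lattice A `grid_lattice`.
#' @param members Integer unit ids.
#' @param rule Contiguity rule, `"rook"` (edge-sharing; the default used for
#'   perimeter patches) or `"queen"`.
#' @return An integer vector of component labels (1, 2, ...) parallel to
#'   `members`.
#' @export
connected_components <- function(lattice, members, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  members <- as.integer(members)
  if (length(members) == 0L) return(integer(0))
  w <- contiguity_weights(lattice, rule)
  comp_labels(members, w$neighbors)
}

# BFS labelling of `members` under neighbour lists
comp_labels <- function(members, neighbors) {
  idx <- match(seq_along(neighbors), members)  # unit -> position in members
  lab <- integer(length(members))
  cur <- 0L
  for (s in seq_along(members)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- members[s]
    lab[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in neighbors[[u]]) {
        p <- idx[v]
        if (!is.na(p) && lab[p] == 0L) {
          lab[p] <- cur
          queue <- c(queue, v)
        }
      }
    }
  }
  lab
}
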