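test_that("regular grid construction lays out units row-major with correct areas", {
  g <- build_regular_grid(30, 40, 1)
  expect_equal(nrow(g), 1200)
  expect_equal(lattice_info(g)$total_area, 1200)
  expect_equal(g$unit_id, seq_len(1200))
  expect_equal(g$row[41], 1L)  # second row starts after 40 cells
  expect_equal(g$col[41], 0L)

  g1 <- build_regular_grid(1, 1, 2)
  expect_equal(nrow(g1), 1)
  expect_equal(lattice_info(g1)$total_area, 4)
  expect_equal(sum(g1$area), lattice_info(g1)$total_area)

  expect_error(build_regular_grid(0, 3), "positive integers")
  expect_error(build_regular_grid(2, 3, 0), "positive length")
})

test_that("rook adjacency of a corner cell follows grid geometry", {
  g <- build_regular_grid(2, 3)
  w <- contiguity_weights(g, "rook")
  # unit 1 is cell (0,0): rook neighbours are (0,1) = id 2 and (1,0) = id 4
  expect_equal(w$neighbors[[1]], c(2L, 4L))
})

test_that("queen weights link 8 interior / 3 corner neighbours and honor self-inclusion", {
  g <- build_regular_grid(5, 5)
  w <- contiguity_weights(g, "queen")
  expect_equal(length(w$neighbors[[13]]), 8L)  # interior cell
  ws <- contiguity_weights(g, "queen", include_self = TRUE)
  expect_equal(length(ws$neighbors[[1]]), 4L)  # corner: 3 neighbours + self
  expect_true(1L %in% ws$neighbors[[1]])
  expect_false(1L %in% w$neighbors[[1]])
})

test_that("distance weights at one cell size reproduce rook links", {
  g <- build_regular_grid(3, 3)
  wd <- contiguity_weights(g, "distance", threshold = 1)
  wr <- contiguity_weights(g, "rook")
  expect_equal(wd$neighbors, wr$neighbors)
  expect_error(contiguity_weights(g, "distance"), "threshold")
})

test_that("weights are symmetric, binary and self-consistent on random lattices", {
  withr::with_seed(42, {
    for (k in 1:5) {
      nr <- sample(2:6, 1)
      nc <- sample(2:6, 1)
      g <- build_regular_grid(nr, nc, runif(1, 0.5, 3))
      for (rule in c("queen", "rook")) {
        for (self in c(FALSE, TRUE)) {
          w <- contiguity_weights(g, rule, include_self = self)
          for (i in seq_len(nrow(g))) {
            nb <- w$neighbors[[i]]
            expect_equal(anyDuplicated(nb), 0L)
            expect_equal(i %in% nb, self)
            for (j in setdiff(nb, i)) expect_true(i %in% w$neighbors[[j]])
          }
        }
      }
    }
  })
})

test_that("patch perimeter counts exposed cell edges", {
  g <- build_regular_grid(4, 4)
  expect_equal(patch_perimeter(g, 1), 4)              # single cell
  expect_equal(patch_perimeter(g, c(1, 2, 5, 6)), 8)  # 2x2 block
  expect_equal(patch_perimeter(g, c(1, 5, 6)), 8)     # L-tromino
  expect_error(patch_perimeter(g, integer(0)), "nonempty")
})

test_that("perimeter is additive over non-adjacent patches and respects the isoperimetric bound", {
  g <- build_regular_grid(6, 6)
  p1 <- patch_perimeter(g, c(1, 2))
  p2 <- patch_perimeter(g, c(29, 30, 35))
  expect_equal(patch_perimeter(g, c(1, 2, 29, 30, 35)), p1 + p2)

  # every <= 6-cell patch has perimeter >= that of the tightest block with
  # the same cell count (exhaustive over subsets of a 3 x 2 window)
  window <- c(1, 2, 3, 7, 8, 9)
  best_block <- c(4, 6, 8, 8, 10, 10)  # minimal lattice perimeter, 1..6 cells
  for (k in 1:6) {
    combs <- utils::combn(window, k)
    for (j in seq_len(ncol(combs))) {
      expect_gte(patch_perimeter(g, combs[, j]), best_block[k])
    }
  }
})

test_that("interior holes contribute to the perimeter", {
  g <- build_regular_grid(5, 5)
  ring <- setdiff(which(g$row %in% 0:2 & g$col %in% 0:2), which(g$row == 1 & g$col == 1))
  expect_equal(patch_perimeter(g, ring), 12 + 4)
})

test_that("grid-csv round trip preserves values and rejects malformed input", {
  g <- build_regular_grid(2, 2)
  g$value <- c(3, 0, 7, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field(g, path, "grid-csv")
  back <- read_field(path, "grid-csv")
  expect_equal(back$value, g$value)
  expect_equal(back$unit_id, g$unit_id)
  expect_equal(lattice_info(back)$total_area, 4)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,col,value", "0,0,1", "0,0,2", "0,1,1", "1,0,1", "1,1,1"), dup)
  expect_error(read_field(dup, "grid-csv"), "duplicate cell \\(row=0, col=0\\)")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,col,value", "0,0,-1", "0,1,2", "1,0,1", "1,1,1"), neg)
  expect_error(read_field(neg, "grid-csv"), "negative count")
})

test_that("geojson round trip preserves polygons, counts and adjacency", {
  g <- build_regular_grid(2, 3)
  g$value <- c(1, 2, 3, 4, 5, 6)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_field(g, path, "geojson")
  back <- read_field(path, "geojson")
  expect_equal(nrow(back), 6)
  expect_equal(back$value, g$value)
  expect_equal(sum(back$value), 21)
  expect_equal(back$area, g$area)
  expect_equal(back$x, g$x)
  expect_equal(back$y, g$y)
  expect_equal(lattice_info(back)$type, "polygon")
  # polygon contiguity agrees with the grid rules
  for (rule in c("rook", "queen")) {
    wp <- contiguity_weights(back, rule)
    wg <- contiguity_weights(g, rule)
    expect_equal(wp$neighbors, wg$neighbors)
  }
  # polygon perimeter agrees with cell-edge counting
  expect_equal(patch_perimeter(back, c(1, 2)), patch_perimeter(g, c(1, 2)))

  # a missing count property is rejected by feature index
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$features[[2]]$properties$count <- NULL
  bad <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_field(bad, "geojson"), "feature 2")
})

test_that("detection output serializes per-unit records", {
  g <- planted_grid(5, 5, 1:2, 1:2, hi = 30)
  det <- detect_hotspots(g, "gstar")
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(det, path, "csv")
  rec <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(rec), 25)
  expect_true(all(c("unit_id", "stat", "p_value", "hotspot", "cluster_id") %in% names(rec)))
  expect_equal(sum(rec$hotspot), sum(det$hotspot))
})
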