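#' Read a gridded count field
#'
#' Two plain-text formats are supported. `grid-csv` is a CSV with columns
#' `row`, `col`, `value` (0-based integer indices, one record per cell,
#' covering a complete rectangle). `geojson` is a FeatureCollection of
#' polygon features, each carrying a non-negative `count` property; this is
#' the pathway for irregular lattices such as merged census grids.
#'
#' @param path File to read.
#' @param format `"grid-csv"` or `"geojson"`.
#' @param cell_size Cell side length assumed for `grid-csv` input.
#' @return A lattice tibble (see [build_regular_grid()]) with an extra
#'   `value` column holding the per-unit counts. For GeoJSON input the
#'   lattice is polygon-typed: centroids and areas come from the ring
#'   geometry (shoelace formula) and the rings are kept in the
#'   `"geometry"` attribute.
#' @export
read_field <- function(path, format = c("grid-csv", "geojson"), cell_size = 1) {
  format <- match.arg(format)
  if (format == "grid-csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("row", "col", "value")
    if (!all(need %in% names(df))) {
      stop("grid-csv must have columns row, col, value", call. = FALSE)
    }
    dup <- duplicated(df[c("row", "col")])
    if (any(dup)) {
      d <- df[which(dup)[1], ]
      stop(sprintf("duplicate cell (row=%d, col=%d) in %s", d$row, d$col, path),
           call. = FALSE)
    }
    if (any(df$value < 0)) {
      d <- df[which(df$value < 0)[1], ]
      stop(sprintf("negative count at (row=%d, col=%d) in %s", d$row, d$col, path),
           call. = FALSE)
    }
    nrows <- max(df$row) + 1L
    ncols <- max(df$col) + 1L
    if (nrow(df) != nrows * ncols || any(df$row < 0) || any(df$col < 0)) {
      stop("grid-csv must cover a complete 0-based rectangle of cells",
           call. = FALSE)
    }
    g <- build_regular_grid(nrows, ncols, cell_size)
    df <- dplyr::arrange(df, .data$row, .data$col)
    g$value <- as.numeric(df$value)
    g
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
    feats <- gj$features
    rings <- vector("list", length(feats))
    value <- numeric(length(feats))
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      if (is.null(f$properties$count)) {
        stop(sprintf("feature %d is missing the `count` property", i), call. = FALSE)
      }
      v <- as.numeric(f$properties$count)
      if (!is.finite(v) || v < 0) {
        stop(sprintf("feature %d has a negative or invalid count", i), call. = FALSE)
      }
      value[i] <- v
      if (!identical(f$geometry$type, "Polygon")) {
        stop(sprintf("feature %d: only Polygon geometry is supported", i),
             call. = FALSE)
      }
      ring <- f$geometry$coordinates[[1]]
      rings[[i]] <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    polygon_lattice(rings, value)
  }
}

# build a polygon-typed lattice from closed rings (first == last vertex)
polygon_lattice <- function(rings, value) {
  cent <- t(vapply(rings, ring_centroid, numeric(2)))
  area <- vapply(rings, ring_area, numeric(1))
  if (any(area <= 0)) stop("every polygon must have positive area", call. = FALSE)
  out <- tibble::tibble(
    unit_id = seq_along(rings),
    row = NA_integer_, col = NA_integer_,
    x = cent[, 1], y = cent[, 2], area = area,
    value = as.numeric(value)
  )
  attr(out, "geometry") <- rings
  new_grid_lattice(out, list(type = "polygon", total_area = sum(area)))
}

ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}

ring_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  cr <- x[-length(x)] * y[-1] - x[-1] * y[-length(y)]
  a <- sum(cr) / 2
  c(sum((x[-length(x)] + x[-1]) * cr), sum((y[-length(y)] + y[-1]) * cr)) / (6 * a)
}

#' Write a count field
#'
#' Inverse of [read_field()]: writing then reading reproduces units,
#' geometry and values exactly.
#'
#' @param grid A lattice tibble with a `value` column.
#' @param path Output file.
#' @param format `"grid-csv"` or `"geojson"`.
#' @export
write_field <- function(grid, path, format = c("grid-csv", "geojson")) {
  format <- match.arg(format)
  if (format == "grid-csv") {
    if (!is_grid(grid)) {
      stop("grid-csv output requires a regular grid lattice", call. = FALSE)
    }
    readr::write_csv(grid[c("row", "col", "value")], path)
  } else {
    write_geojson(grid, path, lapply(seq_len(nrow(grid)), function(i) {
      list(count = grid$value[i])
    }))
  }
  invisible(path)
}

#' Write a detection result
#'
#' Serializes a hotspot labeling as per-unit records: unit id, statistic,
#' p-value, hotspot flag and cluster id (CSV), or the same fields as GeoJSON
#' feature properties alongside the cell polygons.
#'
#' @param detection A `hotspot_detection` tibble (see [detect_hotspots()]).
#' @param path Output file.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_result <- function(detection, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  cols <- c("unit_id", "row", "col", "value", "stat", "p_value",
            "hotspot", "cluster_id")
  cols <- intersect(cols, names(detection))
  if (format == "csv") {
    readr::write_csv(detection[cols], path)
  } else {
    write_geojson(detection, path, lapply(seq_len(nrow(detection)), function(i) {
      list(count = detection$value[i],
           stat = unname(detection$stat[i]),
           p_value = unname(detection$p_value[i]),
           hotspot = unname(detection$hotspot[i]),
           cluster_id = unname(detection$cluster_id[i]))
    }))
  }
  invisible(path)
}

write_geojson <- function(grid, path, props) {
  rings <- unit_rings(grid)
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    list(
      type = "Feature",
      properties = props[[i]],
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(rings[[i]])), function(k) {
          as.numeric(rings[[i]][k, ])
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

# square rings for grid cells, stored rings for polygon lattices
unit_rings <- function(grid) {
  if (!is_grid(grid)) return(attr(grid, "geometry"))
  s <- lattice_info(grid)$cell_size
  lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$col[i] * s; y0 <- grid$row[i] * s
    cbind(c(x0, x0 + s, x0 + s, x0, x0),
          c(y0, y0, y0 + s, y0 + s, y0))
  })
}
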