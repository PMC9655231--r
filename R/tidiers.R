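#' Tidy a hotspot detection
#'
#' One row per reported cluster: id, center/seed unit, cell count, cases
#' captured, statistic (window log-LR for scan, G* z for AMOEBA, max local
#' z otherwise) and p-value.
#'
#' @param x A `hotspot_detection` tibble.
#' @param ... Unused.
#' @export
tidy.hotspot_detection <- function(x, ...) {
  cl <- attr(x, "clusters", exact = TRUE) %||% empty_clusters()
  dplyr::select(cl, -dplyr::any_of("members"))
}

#' Summarize a hotspot detection
#'
#' @param x A `hotspot_detection` tibble.
#' @param ... Unused.
#' @return A one-row tibble: method, alpha, number of clusters, flagged
#'   cells, cases captured, and the smallest cluster p-value.
#' @export
glance.hotspot_detection <- function(x, ...) {
  cl <- attr(x, "clusters", exact = TRUE) %||% empty_clusters()
  tibble::tibble(
    method = attr(x, "method", exact = TRUE),
    alpha = attr(x, "alpha", exact = TRUE),
    n_clusters = nrow(cl),
    n_hotspot_cells = sum(x$hotspot),
    cases_captured = sum(x$value[x$hotspot]),
    min_p = if (nrow(cl)) min(cl$p_value) else NA_real_
  )
}

#' Tidy a local statistic result
#'
#' @param x A `local_stats` tibble.
#' @param ... Unused.
#' @return A tibble with `unit_id`, `stat`, `z`, `p`.
#' @export
tidy.local_stats <- function(x, ...) {
  tibble::as_tibble(x[c("unit_id", "stat", "z", "p")])
}

#' Per-method summary of a benchmark run
#'
#' Means and standard deviations, across replicates, of the main
#' indicators for each detector.
#'
#' @param x A `hotspot_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @export
tidy.hotspot_benchmark <- function(x, ...) {
  if (nrow(x) == 0L) return(tibble::tibble(method = character()))
  keep <- intersect(
    c("hit_rate", "area_ratio", "pai", "dcr", "ssi",
      "precision", "recall", "f1"),
    names(x)
  )
  x |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(keep),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ stats::sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
}
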