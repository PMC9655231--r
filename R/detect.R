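#' Run a hotspot detector
#'
#' Uniform entry point over the four detectors. `"scan"` calls
#' [scan_detect()]; `"gstar"` and `"moran"` compute the local statistic
#' with queen weights and threshold it via [extract_hotspots()];
#' `"amoeba"` calls [amoeba_detect()].
#'
#' @param grid A lattice tibble with a `value` column.
#' @param method One of `"scan"`, `"gstar"`, `"moran"`, `"amoeba"`.
#' @param alpha Significance level (default 0.05).
#' @param n_sim Monte Carlo permutations for scan/AMOEBA (default 999).
#' @param seed Optional integer seed for the Monte Carlo nulls.
#' @param weights Optional [contiguity_weights()]; each detector's
#'   default is queen contiguity (with self for G*).
#' @param correction Multiple-testing correction for the local statistics:
#'   `"none"` (default) or `"bh"`.
#' @param max_fraction Scan window population cap (default 0.5).
#' @return A `hotspot_detection` tibble.
#' @export
detect_hotspots <- function(grid, method = c("scan", "gstar", "moran", "amoeba"),
                            alpha = 0.05, n_sim = 999, seed = NULL,
                            weights = NULL, correction = "none",
                            max_fraction = 0.5) {
  method <- match.arg(method)
  switch(
    method,
    scan = scan_detect(grid, max_fraction = max_fraction, n_sim = n_sim,
                       alpha = alpha, seed = seed),
    gstar = extract_hotspots(
      getis_ord_gstar(grid, weights = weights),
      alpha = alpha, correction = correction
    ),
    moran = extract_hotspots(
      local_morans_i(grid, weights = weights),
      alpha = alpha, correction = correction
    ),
    amoeba = amoeba_detect(grid, n_sim = n_sim, alpha = alpha, seed = seed,
                           weights = weights)
  )
}
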