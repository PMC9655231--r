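#' Concentration indicators for a hotspot set
#'
#' Computes the four case-concentration indicators used to evaluate a
#' detection result without ground truth:
#' \describe{
#'   \item{hit rate}{`n / N`, the share of all cases captured by hotspots;}
#'   \item{area ratio}{`a / A`, the share of the study area they occupy;}
#'   \item{PAI}{prediction accuracy index, `hit_rate / area_ratio` — the
#'     case density inside hotspots standardized by the overall density;}
#'   \item{DCR}{density contrast ratio, `(n/a) / ((N-n)/(A-a))` — hotspot
#'     density relative to the density *outside* the hotspots. DCR exceeds
#'     PAI exactly when the hotspot is denser than the background.}
#' }
#' DCR is undefined (returned as `NA`) when the hotspot covers the whole
#' area or captures every case.
#'
#' All arguments are vectorized, so a table of `(n, a)` pairs can be scored
#' in one call.
#'
#' @param n Cases captured by the hotspots.
#' @param N Total cases in the study area.
#' @param a Hotspot area (same unit as `A`; cells count as area when
#'   `cell_size = 1`).
#' @param A Total study-area area.
#' @return A tibble with columns `hit_rate`, `area_ratio`, `pai`, `dcr`.
#' @examples
#' hit_area_indicators(n = 1857, N = 4585, a = 320, A = 1200)
#' @export
hit_area_indicators <- function(n, N, a, A) {
  if (any(N <= 0) || any(a <= 0) || any(a > A)) {
    stop("need N > 0 and 0 < a <= A", call. = FALSE)
  }
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N", call. = FALSE)
  hit_rate <- n / N
  area_ratio <- a / A
  pai <- hit_rate / area_ratio
  dcr <- ifelse(a < A & n < N, (n / a) / ((N - n) / (A - a)), NA_real_)
  tibble::tibble(hit_rate = hit_rate, area_ratio = area_ratio,
                 pai = pai, dcr = dcr)
}

#' Standardized shape index (SSI)
#'
#' Normalized landscape shape index of a patch (or union of patches):
#' `SSI = 1 - 2 * sqrt(pi * area) / perimeter = 1 - 1 / LSI`, where
#' `LSI = perimeter / (2 * sqrt(pi * area))` compares the patch boundary to
#' the circumference of a circle of equal area. A circle scores 0; values
#' approach 1 as shapes grow more complex. SSI is dimensionless and
#' invariant to rescaling all lengths.
#'
#' For multiple patches, pass the *summed* perimeter and *summed* area.
#'
#' @param perimeter Patch boundary length; must be at least the perimeter
#'   of a circle with the given area.
#' @param area Patch area (positive).
#' @return SSI values in `[0, 1)`.
#' @examples
#' shape_index(4, 1)                    # a unit square, ~0.114
#' shape_index(2 * sqrt(pi * 3), 3)     # a circle, exactly 0
#' @export
shape_index <- function(perimeter, area) {
  if (any(area <= 0)) stop("`area` must be positive", call. = FALSE)
  pmin_circ <- 2 * sqrt(pi * area)
  if (any(perimeter < pmin_circ * (1 - 1e-12))) {
    stop("perimeter is below the circular minimum for this area", call. = FALSE)
  }
  1 - pmin_circ / pmax(perimeter, pmin_circ)
}

#' Confusion counts against a ground-truth mask
#'
#' @param detected,truth Unit masks on the same lattice: either logical
#'   vectors of equal length `n_units`, or integer unit-id vectors (then
#'   `n_units` must be given).
#' @param n_units Number of lattice units (required for id-vector input).
#' @return A tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_counts <- function(detected, truth, n_units = NULL) {
  det <- as_mask(detected, n_units, "detected")
  tru <- as_mask(truth, n_units %||% length(det), "truth")
  if (length(det) != length(tru)) {
    stop("`detected` and `truth` are not aligned to the same lattice",
         call. = FALSE)
  }
  tibble::tibble(
    tp = sum(det & tru), fp = sum(det & !tru),
    fn = sum(!det & tru), tn = sum(!det & !tru)
  )
}

as_mask <- function(m, n_units, what) {
  if (is.logical(m)) return(m)
  if (is.data.frame(m) && "unit_id" %in% names(m)) m <- m$unit_id
  m <- as.integer(m)
  if (is.null(n_units)) {
    stop(sprintf("`n_units` is required when `%s` is given as unit ids", what),
         call. = FALSE)
  }
  out <- logical(n_units)
  out[m] <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision, recall and F1
#'
#' Cell-based accuracy of a detection against ground truth. `F1` is the
#' harmonic mean of precision and recall; it is reported as 0 when both are
#' 0, and an undefined precision (no cells detected) or recall (empty truth)
#' comes back as `NA`.
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative cell
#'   counts (vectorized).
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(tp = 279, fp = 7, fn = 0)
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- dplyr::case_when(
    is.na(precision) | is.na(recall) ~ NA_real_,
    precision + recall == 0 ~ 0,
    TRUE ~ 2 * precision * recall / (precision + recall)
  )
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a detection result
#'
#' Applies the whole evaluation framework to one hotspot labeling:
#' concentration indicators (hit rate, area ratio, PAI, DCR), the patch
#' perimeter and standardized shape index, and — when a ground-truth mask is
#' supplied — the confusion counts with precision/recall/F1. Patch
#' perimeters are summed over rook-connected components of the flagged
#' cells, so diagonal touches do not fuse patches and interior holes count
#' toward the boundary.
#'
#' An empty labeling is reported with `hit_rate = 0`, `area_ratio = 0` and
#' the density/shape indicators `NA`.
#'
#' @param detection A `hotspot_detection` tibble from [detect_hotspots()]
#'   (or any lattice tibble with `value` and logical `hotspot` columns).
#' @param truth Optional ground-truth hotspot mask: logical vector, integer
#'   unit ids, or a tibble with a `unit_id` column.
#' @return A one-row tibble of class `hotspot_evaluation` with columns
#'   `n_cases`, `total_cases`, `area`, `total_area`, `hit_rate`,
#'   `area_ratio`, `pai`, `dcr`, `perimeter`, `ssi` and, with truth,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate <- function(detection, truth = NULL) {
  if (!"hotspot" %in% names(detection) || !"value" %in% names(detection)) {
    stop("`detection` must carry `value` and `hotspot` columns", call. = FALSE)
  }
  info <- lattice_info(detection)
  flagged <- which(detection$hotspot)
  N <- sum(detection$value)
  A <- info$total_area
  if (length(flagged) > 0L) {
    n <- sum(detection$value[flagged])
    a <- sum(detection$area[flagged])
    conc <- hit_area_indicators(n, N, a, A)
    perim <- patch_perimeter(detection, flagged)
    ssi <- shape_index(perim, a)
  } else {
    n <- 0; a <- 0; perim <- NA_real_; ssi <- NA_real_
    conc <- tibble::tibble(hit_rate = 0, area_ratio = 0,
                           pai = NA_real_, dcr = NA_real_)
  }
  out <- tibble::tibble(
    n_cases = n, total_cases = N, area = a, total_area = A,
    hit_rate = conc$hit_rate, area_ratio = conc$area_ratio,
    pai = conc$pai, dcr = conc$dcr,
    perimeter = perim, ssi = ssi
  )
  if (!is.null(truth)) {
    tru <- as_mask(truth, nrow(detection), "truth")
    cc <- confusion_counts(detection$hotspot, tru)
    out <- dplyr::bind_cols(out, cc, precision_recall_f1(cc$tp, cc$fp, cc$fn))
  }
  class(out) <- unique(c("hotspot_evaluation", class(out)))
  out
}
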