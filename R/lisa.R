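#' Getis-Ord G* local statistic
#'
#' For every unit, the share of the study-area total found in its
#' neighbourhood (self included): `G*_i = sum_j w_ij x_j / sum_j x_j`.
#' Standardized scores use the randomization-hypothesis moments for binary
#' weights — the numerator is a simple random sample of `W_i` of the `n`
#' values, so `E[G*_i] = W_i / n` and
#' `var[G*_i] = W_i (n - W_i) s^2 / ((n-1) n^2 xbar^2)` with `s^2` the
#' population (divide-by-n) variance. One-sided upper p-values come from
#' the standard normal, or from a conditional permutation test.
#'
#' A constant field leaves the z-score undefined; the statistic is still
#' returned and `z`/`p` are flagged `NA`.
#'
#' @param grid A lattice tibble with a `value` column.
#' @param weights A [contiguity_weights()] object with `include_self =
#'   TRUE`; defaults to queen contiguity plus self.
#' @param p_method `"analytic"` (normal z-test, the default) or
#'   `"permutation"`.
#' @param n_sim,seed Permutation count and seed when `p_method =
#'   "permutation"`.
#' @return A tibble of class `local_stats`: the input units with `stat`,
#'   `z` and `p` columns; `attr(, "mean_x")` and `attr(, "var_x")` hold the
#'   study-area moments.
#' @export
getis_ord_gstar <- function(grid, weights = NULL,
                            p_method = c("analytic", "permutation"),
                            n_sim = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot("value" %in% names(grid))
  n <- nrow(grid)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  weights <- weights %||% contiguity_weights(grid, "queen", include_self = TRUE)
  if (!isTRUE(weights$include_self)) {
    stop("G* requires weights with include_self = TRUE", call. = FALSE)
  }
  x <- as.numeric(grid$value)
  xbar <- mean(x)
  s2 <- mean((x - xbar)^2)
  W <- lengths(weights$neighbors)
  swx <- vapply(weights$neighbors, function(nb) sum(x[nb]), numeric(1))
  stat <- swx / sum(x)
  if (s2 > 0) {
    denom <- sqrt(s2) * sqrt(W * (n - W) / (n - 1))
    z <- ifelse(W < n, (swx - W * xbar) / denom, NA_real_)
  } else {
    z <- rep(NA_real_, n)
  }
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (p_method == "permutation") {
    p <- lisa_perm_p(swx, weights$neighbors, x, n_sim, seed,
                     stat_fun = function(xp, nb) sum(xp[nb]))
  }
  new_local_stats(grid, stat, z, p, method = "gstar",
                  mean_x = xbar, var_x = s2, weights = weights)
}

#' Local Moran's I
#'
#' Anselin's local indicator of spatial association:
#' `I_i = (x_i - xbar) / S^2 * sum_j w_ij (x_j - xbar)` with `S^2` the
#' population variance and binary weights excluding self. Positive
#' significant values with `x_i > xbar` mark high-high clusters.
#' Standardized scores use the total-randomization moments
#' (`E[I_i] = -W_i/(n-1)`, variance involving the kurtosis ratio
#' `b2 = m4/m2^2`); p-values are one-sided upper.
#'
#' @inheritParams getis_ord_gstar
#' @param weights A [contiguity_weights()] object with `include_self =
#'   FALSE`; defaults to queen contiguity.
#' @return A `local_stats` tibble, as for [getis_ord_gstar()].
#' @export
local_morans_i <- function(grid, weights = NULL,
                           p_method = c("analytic", "permutation"),
                           n_sim = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot("value" %in% names(grid))
  n <- nrow(grid)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  weights <- weights %||% contiguity_weights(grid, "queen", include_self = FALSE)
  if (isTRUE(weights$include_self)) {
    stop("local Moran's I requires weights with include_self = FALSE",
         call. = FALSE)
  }
  x <- as.numeric(grid$value)
  xbar <- mean(x)
  m2 <- mean((x - xbar)^2)
  W <- lengths(weights$neighbors)
  lag <- vapply(weights$neighbors, function(nb) sum(x[nb] - xbar), numeric(1))
  if (m2 > 0) {
    stat <- (x - xbar) / m2 * lag
    b2 <- mean((x - xbar)^4) / m2^2
    EI <- -W / (n - 1)
    VI <- W * (n - b2) / (n - 1) +
      (W^2 - W) * (2 * b2 - n) / ((n - 1) * (n - 2)) -
      (W / (n - 1))^2
    z <- (stat - EI) / sqrt(VI)
  } else {
    stat <- rep(NA_real_, n)
    z <- rep(NA_real_, n)
  }
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (p_method == "permutation" && m2 > 0) {
    p <- lisa_perm_p(stat, weights$neighbors, x, n_sim, seed,
                     stat_fun = function(xp, nb, i) {
                       (xp[i] - xbar) / m2 * sum(xp[nb] - xbar)
                     }, with_index = TRUE)
  }
  new_local_stats(grid, stat, z, p, method = "moran",
                  mean_x = xbar, var_x = m2, weights = weights)
}

# conditional-permutation upper-tail p-values for a per-unit statistic
lisa_perm_p <- function(observed, neighbors, x, n_sim, seed,
                        stat_fun, with_index = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  ge <- integer(n)
  for (s in seq_len(n_sim)) {
    xp <- permute_field(x)
    sim <- if (with_index) {
      vapply(seq_len(n), function(i) stat_fun(xp, neighbors[[i]], i), numeric(1))
    } else {
      vapply(neighbors, function(nb) stat_fun(xp, nb), numeric(1))
    }
    ge <- ge + (sim >= observed)
  }
  (1 + ge) / (1 + n_sim)
}

new_local_stats <- function(grid, stat, z, p, method, mean_x, var_x, weights) {
  out <- grid
  out$stat <- stat
  out$z <- z
  out$p <- p
  attr(out, "lattice") <- lattice_info(grid)
  attr(out, "geometry") <- attr(grid, "geometry")
  attr(out, "method") <- method
  attr(out, "mean_x") <- mean_x
  attr(out, "var_x") <- var_x
  attr(out, "weights_rule") <- weights$rule
  class(out) <- unique(c("local_stats", "grid_lattice", class(out)))
  out
}

#' Extract a hotspot labeling from local statistics
#'
#' Thresholds a [getis_ord_gstar()] or [local_morans_i()] result at a
#' significance level and groups the flagged units into contiguous
#' clusters. For G*, hotspots are units with `p <= alpha` and `z > 0`; for
#' Moran, additionally `stat > 0` and `x_i > xbar` (high-high quadrant
#' only). Benjamini-Hochberg correction of the per-unit p-values is
#' available but off by default, matching the convention of thresholding
#' raw local p-values at 0.05.
#'
#' @param result A `local_stats` tibble.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default) or `"bh"` (Benjamini-Hochberg
#'   step-up, applied before thresholding).
#' @param direction `"high"` (hotspots, default) or `"low"` (cold spots:
#'   lower-tail G*, low-low Moran quadrant).
#' @return A `hotspot_detection` tibble (see [scan_detect()] for the
#'   layout); flagged units grouped into clusters under the weights rule
#'   the statistic was computed with.
#' @export
extract_hotspots <- function(result, alpha = 0.05,
                             correction = c("none", "bh"),
                             direction = c("high", "low")) {
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  method <- attr(result, "method", exact = TRUE)
  if (is.null(method)) stop("`result` is not a local_stats object", call. = FALSE)
  p <- result$p
  # G* cold spots sit in the lower tail of z; Moran low-low clusters still
  # have positive I, so their significance stays in the stored upper tail
  if (direction == "low" && method == "gstar") p <- 1 - p
  if (correction == "bh") p <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p) & p <= alpha
  flagged <- if (method == "gstar") {
    if (direction == "high") sig & result$z > 0 else sig & result$z < 0
  } else {
    quad <- if (direction == "high") {
      result$value > attr(result, "mean_x")
    } else {
      result$value < attr(result, "mean_x")
    }
    sig & !is.na(result$stat) & result$stat > 0 & quad
  }
  ids <- which(flagged)
  rule <- attr(result, "weights_rule") %||% "queen"
  if (rule == "distance") rule <- "queen"
  clusters <- group_clusters(result, ids, result$z, p, rule)
  grid <- result
  grid$p <- NULL
  det <- as_detection(grid, clusters, method = method, alpha = alpha,
                      params = list(correction = correction,
                                    direction = direction),
                      stat = result$stat, p_value = p)
  det$hotspot <- flagged
  det
}

# build the cluster summary tibble for a flagged unit set
group_clusters <- function(lattice, ids, stat, p, rule) {
  if (length(ids) == 0L) return(empty_clusters())
  lab <- connected_components(lattice, ids, rule = rule)
  vals <- if ("value" %in% names(lattice)) lattice$value else rep(NA_real_, nrow(lattice))
  dplyr::bind_rows(lapply(sort(unique(lab)), function(k) {
    mem <- ids[lab == k]
    tibble::tibble(
      cluster_id = k, center_unit = mem[which.max(stat[mem])],
      n_cells = length(mem), cases = sum(vals[mem]),
      stat = max(stat[mem], na.rm = TRUE),
      p_value = min(p[mem], na.rm = TRUE),
      members = list(mem)
    )
  }))
}
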