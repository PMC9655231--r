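#' Grow a single AMOEBA ecotope
#'
#' Region growing around one seed unit, maximizing the G* z-score of the
#' grown neighbourhood. Starting from the seed alone, each round considers
#' the first-order (queen, by default) neighbours of the current ecotope,
#' ranks them by value, and adds the value-ranked prefix that maximizes the
#' statistic; because the statistic at a fixed neighbourhood size is
#' monotone in the added mass, the best prefix is the exact optimizer over
#' all frontier subsets of that size. Frontier units rejected in a round
#' are excluded from all later rounds, and growth stops when no addition
#' strictly increases the statistic.
#'
#' @param grid A lattice tibble with a `value` column (not constant).
#' @param seed_unit Unit id to grow from.
#' @param weights Optional [contiguity_weights()] (without self) defining
#'   first-order neighbours; defaults to queen contiguity.
#' @return A list with `members` (unit ids, seed included), `gstar` (the
#'   final G* z-score), and `generation` (number of growth rounds).
#' @export
grow_ecotope <- function(grid, seed_unit, weights = NULL) {
  stopifnot("value" %in% names(grid))
  x <- as.numeric(grid$value)
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(mean((x - xbar)^2))
  if (s == 0) stop("field is constant: ecotope growth is undefined", call. = FALSE)
  weights <- weights %||% contiguity_weights(grid, "queen", include_self = FALSE)
  nb <- neighbor_arrays(weights)
  res <- amoeba_grow_cpp(nb$flat, nb$off, x, as.integer(seed_unit) - 1L,
                         xbar, s, TRUE)
  list(members = sort(res$members[[1]]), gstar = res$z[1],
       generation = res$generation[1])
}

neighbor_arrays <- function(weights) {
  nbrs <- weights$neighbors
  if (isTRUE(weights$include_self)) {
    nbrs <- lapply(seq_along(nbrs), function(i) setdiff(nbrs[[i]], i))
  }
  list(flat = as.integer(unlist(nbrs) - 1L),
       off = as.integer(cumsum(c(0L, lengths(nbrs)))))
}

#' AMOEBA hotspot detection
#'
#' Grows an ecotope from every unit, tests the grown statistics against a
#' Monte Carlo null obtained by regrowing every seed position on permuted
#' fields, and resolves overlaps among significant ecotopes greedily:
#' descending by statistic, discarding any ecotope that overlaps an
#' already-accepted one. The union of surviving ecotopes is the hotspot
#' labeling. Only positive-direction (high-value) ecotopes are reported.
#'
#' The null model matters twice here. First, the reference field:
#' `null = "rescatter"` (default) redistributes the individual cases over
#' units uniformly at random (multinomial), matching the constant-risk
#' null the scan statistic uses; `"permute"` relabels the observed cell
#' totals across units instead, which conditions on the observed value
#' distribution — including any heavy upper tail, which region growing can
#' chain into large null ecotopes, costing power when hotspots hold much
#' of the mass. Second, the reference statistic: `null_scope = "max"`
#' (default) compares each ecotope with the null distribution of the
#' *maximum* grown statistic over all seeds — a family-wise convention
#' under which the expected flagged area on a pure-noise field stays at or
#' below `alpha` — while `"seed"` compares each ecotope only with
#' regrowths from its own seed position, a per-seed test whose union of
#' marginal ecotopes can flag well over `alpha` of a noise field.
#'
#' @param grid A lattice tibble with a `value` column.
#' @param n_sim Number of Monte Carlo replicates (default 999).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed for the Monte Carlo null.
#' @param weights Optional contiguity weights (without self); queen by
#'   default.
#' One ecotope is grown per unit, so the per-seed test is run n times at
#' once and, like any uncorrected battery of local tests, flags a share of
#' a pure-noise field (roughly `alpha` of the seeds, each carrying a small
#' ecotope). `correction = "bh"` applies the Benjamini-Hochberg step-up
#' across the n per-seed p-values before thresholding; note that with
#' Monte Carlo p-values the BH threshold can fall below the attainable
#' floor `1/(1 + n_sim)`, in which case nothing is flagged — raise `n_sim`
#' accordingly. Reported cluster p-values are always the raw per-seed
#' Monte Carlo p-values.
#'
#' @param null `"rescatter"` (default) or `"permute"`; see Details.
#' @param null_scope `"seed"` (per-seed reference, default) or `"max"`
#'   (family-wise reference).
#' @param correction Multiplicity handling across the n per-seed tests
#'   when `null_scope = "seed"`: `"none"` (default, the conventional
#'   per-ecotope test) or `"bh"`.
#' @return A `hotspot_detection` tibble (see [scan_detect()] for the
#'   layout); each accepted ecotope is one cluster, `stat` holding its G*
#'   z-score.
#' @export
amoeba_detect <- function(grid, n_sim = 999, alpha = 0.05, seed = NULL,
                          weights = NULL, null = c("rescatter", "permute"),
                          null_scope = c("seed", "max"),
                          correction = c("none", "bh")) {
  null <- match.arg(null)
  null_scope <- match.arg(null_scope)
  correction <- match.arg(correction)
  stopifnot("value" %in% names(grid))
  x <- as.numeric(grid$value)
  n <- length(x)
  if (sum(x) <= 0) stop("field has no cases: nothing to detect", call. = FALSE)
  xbar <- mean(x)
  s <- sqrt(mean((x - xbar)^2))
  if (s == 0) stop("field is constant: ecotope growth is undefined", call. = FALSE)
  weights <- weights %||% contiguity_weights(grid, "queen", include_self = FALSE)
  nb <- neighbor_arrays(weights)
  seeds <- seq_len(n) - 1L

  obs <- amoeba_grow_cpp(nb$flat, nb$off, x, as.integer(seeds), xbar, s, TRUE)
  if (!is.null(seed)) set.seed(seed)
  V <- if (null == "permute") {
    replicate(n_sim, permute_field(x))
  } else {
    replicate(n_sim, rescatter_field(x))
  }
  nulls <- amoeba_null_cpp(nb$flat, nb$off, V, as.integer(seeds))
  if (null_scope == "max") {
    null_max <- apply(nulls, 2, max)
    pvals <- vapply(obs$z, mc_pvalue, numeric(1), draws = null_max)
    psel <- pvals
  } else {
    pvals <- (1 + rowSums(nulls >= obs$z)) / (1 + n_sim)
    psel <- if (correction == "bh") stats::p.adjust(pvals, "BH") else pvals
  }

  keep <- which(psel <= alpha & obs$z > 0)
  keep <- keep[order(-obs$z[keep], obs$size[keep], keep)]
  taken <- logical(n)
  clusters <- list()
  for (i in keep) {
    mem <- obs$members[[i]]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    clusters[[length(clusters) + 1L]] <- tibble::tibble(
      cluster_id = length(clusters) + 1L,
      center_unit = i,
      n_cells = length(mem),
      cases = sum(x[mem]),
      stat = obs$z[i],
      p_value = pvals[i],
      members = list(sort(mem))
    )
  }
  cl <- if (length(clusters)) dplyr::bind_rows(clusters) else empty_clusters()
  as_detection(grid, cl, method = "amoeba", alpha = alpha,
               params = list(n_sim = n_sim, seed = seed, rule = weights$rule,
                             null = null, null_scope = null_scope,
                             correction = correction))
}
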