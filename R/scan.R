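#' Poisson likelihood ratio of a scan window
#'
#' Likelihood ratio comparing the observed case count inside a window with
#' its expectation under the constant-risk null:
#' `LR = (c/mu)^c * ((C-c)/(C-mu))^(C-c)` when `c > mu`, and 1 otherwise
#' (one-sided: only excesses, never deficits, score as hotspots). Computed
#' in log space for numerical stability.
#'
#' @param c Observed cases inside the window (`0 <= c <= C`), vectorized.
#' @param mu Expected cases inside (`0 < mu < C`).
#' @param C Total cases in the study area.
#' @param log Return the log likelihood ratio instead?
#' @return The (log) likelihood ratio.
#' @examples
#' poisson_lr(10, 5, 100)   # ~7.89
#' poisson_lr(0, 5, 100)    # 1: a deficit is not a hotspot
#' @export
poisson_lr <- function(c, mu, C, log = FALSE) {
  if (any(mu <= 0) || any(mu >= C)) {
    stop("`mu` must satisfy 0 < mu < C", call. = FALSE)
  }
  if (any(c < 0) || any(c > C)) stop("need 0 <= c <= C", call. = FALSE)
  llr <- ifelse(
    c > mu,
    c * base::log(c / mu) +
      ifelse(C > c, (C - c) * base::log((C - c) / (C - mu)), 0),
    0
  )
  if (log) llr else exp(llr)
}

# Distance-ordered window geometry shared by enumerate_windows() and
# scan_detect(). For each center: units sorted by centroid distance (ties
# broken by unit id), and the valid prefix lengths = ends of distance tie
# groups whose cumulative population share is within `max_fraction` (the
# smallest window per center is always kept so every unit yields a window).
scan_geometry <- function(lattice, max_fraction, pop) {
  n <- nrow(lattice)
  P <- sum(pop)
  ord <- vector("list", n)
  bnd <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (lattice$x - lattice$x[i])^2 + (lattice$y - lattice$y[i])^2
    o <- order(d2, seq_len(n))
    ds <- d2[o]
    is_end <- c(ds[-n] < ds[-1] * (1 - 1e-12), TRUE)
    cum_p <- cumsum(pop[o])
    keep <- which(is_end & cum_p <= max_fraction * P * (1 + 1e-12))
    if (length(keep) == 0L) keep <- which(is_end)[1]
    last <- keep[length(keep)]
    ord[[i]] <- o[seq_len(last)]
    bnd[[i]] <- keep
  }
  list(
    ord_flat = as.integer(unlist(ord) - 1L),
    ord_off = as.integer(cumsum(c(0L, lengths(ord)))),
    b_flat = as.integer(unlist(bnd)),
    b_off = as.integer(cumsum(c(0L, lengths(bnd)))),
    ord = ord, P = P
  )
}

#' Enumerate circular scan windows
#'
#' All distinct windows considered by the scan statistic: for every unit, a
#' circle centered on its centroid at every distinct centroid-distance
#' radius, truncated when the window's population share exceeds
#' `max_fraction`. Duplicate member sets (identical windows reached from
#' different centers) are removed. Intended for inspection and for oracle
#' tests on small lattices; [scan_detect()] uses the same geometry without
#' materializing member sets.
#'
#' @param lattice A lattice tibble; if it has a `value` column, observed
#'   cases `c` and expectations `mu` are filled in.
#' @param max_fraction Maximum share of the background population a window
#'   may cover (default 0.5).
#' @param pop Optional per-unit population; defaults to 1 per unit.
#' @return A tibble with columns `center_unit`, `radius`, `n_members`,
#'   `members` (list-column of unit ids) and, given values, `c` and `mu`.
#' @export
enumerate_windows <- function(lattice, max_fraction = 0.5, pop = NULL) {
  if (nrow(lattice) == 0L) stop("lattice is empty", call. = FALSE)
  pop <- pop %||% rep(1, nrow(lattice))
  geo <- scan_geometry(lattice, max_fraction, pop)
  rows <- list()
  seen <- new.env(hash = TRUE)
  k <- 0L
  for (i in seq_len(nrow(lattice))) {
    o <- geo$ord[[i]]
    b0 <- geo$b_off[i] + 1L
    b1 <- geo$b_off[i + 1L]
    for (b in geo$b_flat[seq(b0, b1)]) {
      mem <- sort(o[seq_len(b)])
      key <- paste(mem, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        center_unit = i,
        radius = sqrt((lattice$x[o[b]] - lattice$x[i])^2 +
                        (lattice$y[o[b]] - lattice$y[i])^2),
        n_members = b,
        members = list(mem)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if ("value" %in% names(lattice)) {
    C <- sum(lattice$value)
    out$c <- vapply(out$members, function(m) sum(lattice$value[m]), numeric(1))
    out$mu <- C * vapply(out$members, function(m) sum(pop[m]), numeric(1)) /
      sum(pop)
  }
  out
}

#' Poisson spatial scan detection
#'
#' The circular spatial scan statistic under the Poisson constant-risk
#' model. Windows of every radius (up to the population cap) are scored
#' with [poisson_lr()] using `mu = C * (window population share)`; the
#' maximum log-LR is tested against its Monte Carlo null distribution
#' obtained by permuting cell values, and secondary clusters are reported
#' greedily in descending LR, skipping windows that overlap an
#' already-reported cluster (each tested against the same max-LR null).
#' Ties in LR resolve to the smaller window, then the lower center id.
#'
#' @param grid A lattice tibble with a `value` column of case counts.
#' @param max_fraction Window population cap as a share of the total
#'   (default 0.5).
#' @param n_sim Number of Monte Carlo permutations (default 999).
#' @param alpha Significance level for reported clusters (default 0.05).
#' @param seed Optional integer seed for the permutation null.
#' @param pop Optional per-unit background population (default: 1 per
#'   unit, the uniform-risk model appropriate for equal-area cells).
#' @param null One of `"permute"` (relabel the observed cell values across
#'   units; the default) or `"rescatter"` (multinomial reallocation of the
#'   individual cases over units).
#' @return A `hotspot_detection` tibble: the input units with `stat`
#'   (the window log-LR for units in a reported cluster), `p_value`,
#'   `hotspot` and `cluster_id` columns. Cluster-level summaries are in
#'   `attr(, "clusters")` and [tidy()] returns them.
#' @export
scan_detect <- function(grid, max_fraction = 0.5, n_sim = 999, alpha = 0.05,
                        seed = NULL, pop = NULL, null = c("permute", "rescatter")) {
  null <- match.arg(null)
  stopifnot("value" %in% names(grid))
  n <- nrow(grid)
  values <- as.numeric(grid$value)
  C <- sum(values)
  if (C <= 0) stop("field has no cases: nothing to detect", call. = FALSE)
  pop <- pop %||% rep(1, n)
  geo <- scan_geometry(grid, max_fraction, pop)

  sc <- scan_score_cpp(geo$ord_flat, geo$ord_off, geo$b_flat, geo$b_off,
                       values, pop, C, geo$P)
  wins <- tibble::tibble(center = sc$center, len = sc$len,
                         cases = sc$cases, llr = sc$llr)

  if (!is.null(seed)) set.seed(seed)
  V <- if (null == "permute") {
    replicate(n_sim, permute_field(values))
  } else {
    replicate(n_sim, rescatter_field(values, pop))
  }
  null_max <- scan_null_max_cpp(geo$ord_flat, geo$ord_off, geo$b_flat,
                                geo$b_off, V, pop, C, geo$P)

  # greedy non-overlapping clusters in descending LR
  cand <- wins[wins$llr > 0, ]
  cand <- cand[order(-cand$llr, cand$len, cand$center), ]
  taken <- logical(n)
  clusters <- list()
  for (k in seq_len(nrow(cand))) {
    p <- mc_pvalue(cand$llr[k], null_max)
    if (p > alpha) break  # llr is non-increasing, so p can only grow
    mem <- geo$ord[[cand$center[k]]][seq_len(cand$len[k])]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    clusters[[length(clusters) + 1L]] <- tibble::tibble(
      cluster_id = length(clusters) + 1L,
      center_unit = cand$center[k],
      n_cells = cand$len[k],
      cases = cand$cases[k],
      stat = cand$llr[k],
      p_value = p,
      members = list(sort(mem))
    )
  }
  cl <- if (length(clusters)) dplyr::bind_rows(clusters) else empty_clusters()
  as_detection(grid, cl, method = "scan", alpha = alpha,
               params = list(max_fraction = max_fraction, n_sim = n_sim,
                             seed = seed, null = null))
}

empty_clusters <- function() {
  tibble::tibble(cluster_id = integer(), center_unit = integer(),
                 n_cells = integer(), cases = numeric(), stat = numeric(),
                 p_value = numeric(), members = list())
}

# assemble the common per-unit detection tibble from cluster memberships
as_detection <- function(grid, clusters, method, alpha, params,
                         stat = NULL, p_value = NULL) {
  n <- nrow(grid)
  out <- grid
  out$stat <- stat %||% rep(NA_real_, n)
  out$p_value <- p_value %||% rep(NA_real_, n)
  out$hotspot <- FALSE
  out$cluster_id <- NA_integer_
  for (k in seq_len(nrow(clusters))) {
    mem <- clusters$members[[k]]
    out$hotspot[mem] <- TRUE
    out$cluster_id[mem] <- clusters$cluster_id[k]
    if (is.null(stat)) out$stat[mem] <- clusters$stat[k]
    if (is.null(p_value)) out$p_value[mem] <- clusters$p_value[k]
  }
  attr(out, "lattice") <- lattice_info(grid)
  attr(out, "geometry") <- attr(grid, "geometry")
  attr(out, "clusters") <- clusters
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "params") <- params
  class(out) <- unique(c("hotspot_detection", "grid_lattice", class(out)))
  out
}
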