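#' Permute a count field across units
#'
#' Draws one conditional-randomization replicate: the observed multiset of
#' cell values is kept and randomly relabelled across units, so the total is
#' preserved exactly. All detectors use this shared null model for their
#' Monte Carlo tests. Randomness comes from R's global RNG; set a seed (or
#' pass `seed =` to the detector entry points) for reproducibility.
#'
#' @param values Numeric vector of per-unit counts.
#' @return A uniformly random permutation of `values`.
#' @export
permute_field <- function(values) {
  if (length(values) == 0L) stop("field is empty", call. = FALSE)
  values[sample.int(length(values))]
}

#' Monte Carlo permutation p-value
#'
#' Rank-based significance with the add-one convention:
#' `p = (1 + #\{draws >= observed\}) / (1 + n_sim)`. Ties count against the
#' observed statistic (conservative), and the observed value itself stands
#' in as one realization of the null, so `p` lies in `(0, 1]` and the
#' smallest attainable value with 999 permutations is 0.001.
#'
#' @param observed Observed statistic.
#' @param draws Numeric vector of statistic values from permuted fields.
#' @return The permutation p-value.
#' @examples
#' mc_pvalue(10, rep(1, 999))  # 0.001
#' @export
mc_pvalue <- function(observed, draws) {
  if (length(draws) == 0L) stop("null distribution is empty", call. = FALSE)
  (1 + sum(draws >= observed)) / (1 + length(draws))
}

#' Case-rescatter null replicate
#'
#' Alternative null for the scan statistic: instead of relabelling cell
#' totals, the `N` individual cases are re-scattered over units with
#' probability proportional to population (uniform by default), i.e. a
#' multinomial reallocation. The field total is preserved.
#'
#' @param values Numeric vector of per-unit counts (must sum to a whole
#'   number of cases).
#' @param pop Optional per-unit population weights.
#' @return A resampled count vector with the same total.
#' @export
rescatter_field <- function(values, pop = NULL) {
  total <- sum(values)
  if (length(values) == 0L || total <= 0) stop("field has no cases", call. = FALSE)
  prob <- if (is.null(pop)) rep(1, length(values)) else pop
  as.numeric(stats::rmultinom(1, size = round(total), prob = prob))
}
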