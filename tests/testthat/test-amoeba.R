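test_that("a flat neighbourhood leaves the ecotope at its seed", {
  g <- build_regular_grid(6, 6)
  g$value <- rep(1, 36)
  g$value[1] <- 10  # the only relief: everything around any seed is flat
  eco <- grow_ecotope(g, seed_unit = 22)
  expect_equal(eco$members, 22L)
  expect_equal(eco$generation, 0L)

  gc <- build_regular_grid(4, 4)
  gc$value <- rep(3, 16)
  expect_error(grow_ecotope(gc, 1), "constant")
})

test_that("growth recovers a planted high block exactly", {
  g <- planted_grid(6, 6, 2:3, 2:3, hi = 9, lo = 1)
  block <- which(g$value == 9)
  for (seed in block) {
    eco <- grow_ecotope(g, seed)
    expect_equal(eco$members, block)
  }
  # exhaustive check on a cropped 4x4 copy of the same configuration
  g4 <- planted_grid(4, 4, 1:2, 1:2, hi = 9, lo = 1)
  eco4 <- grow_ecotope(g4, which(g4$value == 9)[1])
  expect_equal(eco4$gstar, oracle_amoeba_max(g4, which(g4$value == 9)[1]),
               tolerance = 1e-10)
})

test_that("growth is bounded by the exhaustive connected-subset maximum", {
  # The growth rule is the published one-round-lookahead procedure, so its
  # statistic can never exceed -- and from seeds inside a genuine cluster
  # attains -- the exhaustive maximum over connected supersets of the seed.
  withr::with_seed(61, {
    g <- build_regular_grid(4, 4)
    g$value <- rpois(16, 3)
    for (seed in c(1, 6, 16)) {
      expect_lte(grow_ecotope(g, seed)$gstar,
                 oracle_amoeba_max(g, seed) + 1e-10)
    }
  })
})

test_that("each round's prefix choice is optimal over all frontier subsets", {
  # the value-sorted-prefix device: for a fixed ecotope, the best subset of
  # frontier units to add is always a prefix of the value-ranked frontier
  # (checked exhaustively over all 2^|F| subsets for random states)
  zfun <- function(sum_s, W, n, xbar, s) {
    (sum_s - W * xbar) / (s * sqrt(W * (n - W) / (n - 1)))
  }
  withr::with_seed(62, {
    for (rep in 1:20) {
      n <- 20
      x <- rpois(n, 3) + runif(n) * 1e-6  # break ties, keep integers in spirit
      xbar <- mean(x); s <- sqrt(mean((x - xbar)^2))
      W0 <- sample(1:6, 1)
      S <- sample(n, W0)
      Fr <- sample(setdiff(seq_len(n), S), sample(2:8, 1))
      sum_s <- sum(x[S])
      # exhaustive over subsets of the frontier
      best_exh <- -Inf
      for (m in seq_len(2^length(Fr)) - 1L) {
        sel <- Fr[bitwAnd(m, bitwShiftL(1L, seq_along(Fr) - 1L)) != 0L]
        k <- length(sel)
        if (W0 + k >= n) next
        z <- zfun(sum_s + sum(x[sel]), W0 + k, n, xbar, s)
        best_exh <- max(best_exh, z)
      }
      # prefixes of the value-sorted frontier only
      o <- Fr[order(-x[Fr])]
      best_pref <- -Inf
      for (k in 0:length(o)) {
        if (W0 + k >= n) break
        z <- zfun(sum_s + sum(x[o[seq_len(k)]]), W0 + k, n, xbar, s)
        best_pref <- max(best_pref, z)
      }
      expect_equal(best_pref, best_exh, tolerance = 1e-10)
    }
  })
})

test_that("from seeds inside a planted cluster, growth attains the exhaustive maximum", {
  g <- build_regular_grid(4, 4)
  g$value <- rep(1, 16)
  block <- which(g$row %in% 1:2 & g$col %in% 1:2)
  g$value[block] <- c(7, 8, 9, 6)  # heterogeneous upper-tail cluster
  for (seed in block) {
    expect_equal(grow_ecotope(g, seed)$gstar, oracle_amoeba_max(g, seed),
                 tolerance = 1e-10)
  }
})

test_that("ecotope growth is deterministic and connected", {
  withr::with_seed(71, {
    g <- build_regular_grid(8, 8)
    g$value <- rpois(64, 3)
    e1 <- grow_ecotope(g, 28)
    e2 <- grow_ecotope(g, 28)
    expect_identical(e1, e2)
    expect_true(28 %in% e1$members)
    lab <- connected_components(g, e1$members, rule = "queen")
    expect_equal(length(unique(lab)), 1L)
  })
})

test_that("detection flags a planted block with the smallest attainable p-value", {
  withr::with_seed(81, {
    g <- build_regular_grid(8, 8)
    g$value <- rpois(64, 2)
    block <- which(g$row %in% 2:3 & g$col %in% 4:5)
    g$value[block] <- 30
    det <- amoeba_detect(g, n_sim = 999, seed = 9)
    expect_true(all(block %in% which(det$hotspot)))
    cl <- attr(det, "clusters")
    expect_equal(min(cl$p_value), 0.001)
    # determinism contract
    det2 <- amoeba_detect(g, n_sim = 999, seed = 9)
    expect_equal(det$hotspot, det2$hotspot)
    expect_equal(attr(det2, "clusters")$stat, cl$stat)
  })
})

test_that("accepted ecotopes do not overlap", {
  withr::with_seed(91, {
    g <- build_regular_grid(8, 8)
    g$value <- rpois(64, 2)
    g$value[c(1, 2, 9, 10)] <- 25
    g$value[c(55, 56, 63, 64)] <- 25
    # the relabelling null conditions on the two extreme blocks, keeping
    # both significant on this tiny lattice; the point here is the greedy
    # overlap resolution, which is null-independent
    det <- amoeba_detect(g, n_sim = 199, seed = 10, null = "permute")
    cl <- attr(det, "clusters")
    expect_gte(nrow(cl), 2)
    expect_equal(anyDuplicated(unlist(cl$members)), 0L)
    expect_true(all(cl$p_value <= 0.05))
    expect_true(all(cl$stat > 0))
  })
})

test_that("a zero or constant field is rejected", {
  g <- build_regular_grid(3, 3)
  g$value <- rep(0, 9)
  expect_error(amoeba_detect(g, n_sim = 9), "no cases")
  g$value <- rep(2, 9)
  expect_error(amoeba_detect(g, n_sim = 9), "constant")
})
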