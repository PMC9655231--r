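test_that("concentration indicators reproduce direct arithmetic", {
  r <- hit_area_indicators(n = 1857, N = 4585, a = 320, A = 1200)
  expect_equal(round(100 * r$hit_rate, 1), 40.5)
  expect_equal(round(100 * r$area_ratio, 2), 26.67)
  expect_equal(round(r$pai, 2), 1.52)
  expect_equal(round(r$dcr, 2), 1.87)

  r2 <- hit_area_indicators(n = 1906, N = 4585, a = 286, A = 1200)
  expect_equal(round(100 * r2$hit_rate, 1), 41.6)
  expect_equal(round(r2$pai, 2), 1.74)
  expect_equal(round(r2$dcr, 2), 2.27)

  whole <- hit_area_indicators(n = 10, N = 10, a = 5, A = 5)
  expect_equal(whole$pai, 1)
  expect_true(is.na(whole$dcr))

  expect_error(hit_area_indicators(5, 10, 0, 4), "0 < a <= A")
  expect_error(hit_area_indicators(11, 10, 2, 4), "0 <= n <= N")
})

test_that("PAI and DCR identities hold across random valid inputs", {
  withr::with_seed(11, {
    for (k in 1:50) {
      N <- runif(1, 10, 1e4)
      n <- runif(1, 0, N * 0.999)
      A <- runif(1, 10, 1e4)
      a <- runif(1, A * 0.001, A * 0.999)
      r <- hit_area_indicators(n, N, a, A)
      expect_equal(r$pai, r$hit_rate / r$area_ratio)
      expect_equal(r$dcr, r$pai * (1 - r$area_ratio) / (1 - r$hit_rate))
      expect_equal(r$dcr > r$pai, r$hit_rate > r$area_ratio)
    }
  })
})

test_that("shape index is 0 for circles, positive for lattice patches, scale invariant", {
  expect_equal(shape_index(2 * sqrt(pi * 7), 7), 0)
  expect_equal(shape_index(4, 1), 1 - sqrt(pi) / 2)
  expect_equal(round(shape_index(6, 2), 4), 0.1645)
  withr::with_seed(13, {
    for (k in 1:20) {
      a <- runif(1, 0.1, 50)
      p <- 2 * sqrt(pi * a) * runif(1, 1, 10)
      s <- shape_index(p, a)
      expect_gte(s, 0)
      expect_lt(s, 1)
      kk <- runif(1, 0.1, 10)  # rescale all lengths
      expect_equal(shape_index(kk * p, kk^2 * a), s)
    }
  })
  expect_error(shape_index(1, 1), "circular minimum")
})

test_that("confusion counts partition the lattice", {
  cc <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(cc), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  same <- confusion_counts(1:5, 1:5, n_units = 10)
  expect_equal(same$fp, 0L)
  expect_equal(same$fn, 0L)

  none <- confusion_counts(logical(10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(none$tp, 0L)
  expect_equal(none$fn, 4L)

  big <- confusion_counts(1:286, 8:286, n_units = 1200)
  expect_equal(unlist(big[c("tp", "fp", "fn")]), c(tp = 279L, fp = 7L, fn = 0L))

  expect_error(confusion_counts(logical(5), logical(6)), "not aligned")
})

test_that("precision/recall/F1 follow their definitions and edge conventions", {
  r <- precision_recall_f1(tp = 231, fp = 89, fn = 48)
  expect_equal(round(100 * r$recall, 1), 82.8)
  expect_equal(round(r$f1, 3), 0.771)

  r2 <- precision_recall_f1(tp = 279, fp = 7, fn = 0)
  expect_equal(round(100 * r2$precision, 1), 97.6)
  expect_equal(r2$recall, 1)
  expect_equal(round(r2$f1, 3), 0.988)

  miss <- precision_recall_f1(tp = 0, fp = 5, fn = 5)
  expect_equal(miss$precision, 0)
  expect_equal(miss$recall, 0)
  expect_equal(miss$f1, 0)

  undef <- precision_recall_f1(tp = 0, fp = 0, fn = 5)
  expect_true(is.na(undef$precision))

  # harmonic mean lies between precision and recall
  withr::with_seed(17, {
    tp <- sample(1:100, 20, TRUE)
    fp <- sample(0:100, 20, TRUE)
    fn <- sample(0:100, 20, TRUE)
    r <- precision_recall_f1(tp, fp, fn)
    expect_true(all(r$f1 >= pmin(r$precision, r$recall) - 1e-12))
    expect_true(all(r$f1 <= pmax(r$precision, r$recall) + 1e-12))
  })
})

test_that("evaluate() assembles all indicators from a labeling", {
  g <- build_regular_grid(5, 5)
  g$value <- rep(2, 25)

  all_units <- g
  all_units$hotspot <- TRUE
  ev <- evaluate(all_units)
  expect_equal(ev$hit_rate, 1)
  expect_equal(ev$area_ratio, 1)

  two <- g
  two$hotspot <- seq_len(25) %in% c(1, 13)  # disjoint single cells
  ev2 <- evaluate(two)
  expect_equal(ev2$perimeter, 8)
  expect_equal(ev2$area, 2)
  expect_equal(ev2$ssi, shape_index(8, 2))

  none <- g
  none$hotspot <- FALSE
  ev3 <- evaluate(none)
  expect_equal(ev3$hit_rate, 0)
  expect_equal(ev3$area_ratio, 0)
  expect_true(is.na(ev3$pai) && is.na(ev3$dcr) && is.na(ev3$ssi))

  # truth-based block appears only when truth is supplied
  expect_false("f1" %in% names(ev2))
  ev4 <- evaluate(two, truth = c(1, 2))
  expect_equal(ev4$tp, 1L)
  expect_equal(ev4$fp, 1L)
  expect_equal(ev4$fn, 1L)
})

test_that("a Table-2-style labeling of 320 cells capturing 1857 of 4585 cases gives PAI 1.52", {
  g <- build_regular_grid(30, 40)
  hot <- seq_len(320)
  g$value <- rep(0, 1200)
  # distribute 1857 cases over the flagged cells and 2728 over the rest
  g$value[hot] <- c(rep(6, 257), rep(5, 63))
  g$value[321:1200] <- c(rep(4, 88), rep(3, 792))
  stopifnot(sum(g$value[hot]) == 1857, sum(g$value) == 4585)
  g$hotspot <- seq_len(1200) %in% hot
  ev <- evaluate(g)
  expect_equal(round(ev$pai, 2), 1.52)
  expect_equal(round(ev$dcr, 2), 1.87)
})
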