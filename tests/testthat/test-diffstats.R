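test_that("s1 matches a hand median/MAD computation on the worked example", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  s <- s1_statistic(x, y)
  expect_equal(s$M_x, 0.3)
  expect_equal(s$M_y, 0.4)
  expect_equal(s$omega_x, 1.4826 * 0.1)
  expect_equal(s$omega_y, 1.4826 * 0.1)
  expect_equal(s$s_xy, -0.1 / (2 * 1.4826 * 0.1))
  expect_equal(s$S1, abs(s$s_xy))
})

test_that("s1 agrees with the naive sort-based oracle on 1000 random pairs", {
  set.seed(21)
  for (i in 1:1000) {
    nx <- sample(2:40, 1); ny <- sample(2:40, 1)
    x <- stats::runif(nx); y <- stats::runif(ny)
    s <- s1_statistic(x, y)
    expect_equal(s$s_xy, naive_s1(x, y), tolerance = 1e-12)
  }
})

test_that("s1 algebraic properties hold exactly", {
  set.seed(22)
  for (i in 1:25) {
    x <- stats::runif(sample(3:20, 1)); y <- stats::runif(sample(3:20, 1))
    s <- s1_statistic(x, y)
    # identical groups -> 0
    expect_identical(s1_statistic(x, x)$s_xy, 0)
    # antisymmetry and symmetry of the magnitude
    swapped <- s1_statistic(y, x)
    expect_identical(swapped$s_xy, -s$s_xy)
    expect_identical(swapped$S1, s$S1)
    expect_gte(s$S1, 0)
    # shift invariance
    d <- stats::runif(1, -5, 5)
    expect_equal(s1_statistic(x + d, y + d)$s_xy, s$s_xy, tolerance = 1e-12)
    # positive scale invariance
    a <- stats::runif(1, 0.1, 10)
    expect_equal(s1_statistic(a * x, a * y)$s_xy, s$s_xy, tolerance = 1e-12)
  }
})

test_that("zero-denominator cases follow the degenerate-scale policy", {
  same <- s1_statistic(rep(0.4, 5), rep(0.4, 7))
  expect_identical(same$s_xy, 0)
  expect_false(same$degenerate)
  diff <- s1_statistic(rep(0.2, 5), rep(0.7, 7))
  expect_true(diff$degenerate)
  expect_true(is.na(diff$s_xy))
})

test_that("the resampling kernel reproduces an R-level reimplementation", {
  set.seed(23)
  pool <- stats::runif(200)
  n_iter <- 50; n_x <- 6; n_y <- 9
  set.seed(77)
  got <- ccnet:::.null_s1_cpp(pool, n_iter, n_x, n_y, 1.4826)
  set.seed(77)
  want <- vapply(seq_len(n_iter), function(i) {
    ix <- floor(stats::runif(n_x) * length(pool)) + 1L
    iy <- floor(stats::runif(n_y) * length(pool)) + 1L
    s1_statistic(pool[ix], pool[iy])$S1
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("null thresholds are reproducible from the seed", {
  set.seed(24)
  w <- stats::runif(500)
  n1 <- build_null(w, n_x = 10, n_y = 12, pool_size = 200, n_iter = 500,
                   quantile_level = 0.99, seed = 99)
  n2 <- build_null(w, n_x = 10, n_y = 12, pool_size = 200, n_iter = 500,
                   quantile_level = 0.99, seed = 99)
  expect_identical(n1$threshold, n2$threshold)
  n3 <- build_null(w, n_x = 10, n_y = 12, pool_size = 200, n_iter = 500,
                   quantile_level = 0.99, seed = 100)
  expect_false(identical(n1$threshold, n3$threshold))
})

test_that("a constant pool triggers the degenerate policy everywhere", {
  null <- build_null(rep(0.3, 100), n_x = 5, n_y = 5, pool_size = 50,
                     n_iter = 100, quantile_level = 0.99, seed = 5)
  # every draw has zero MADs and equal medians -> statistic 0
  expect_identical(unique(null$s1), 0)
  expect_identical(null$threshold, 0)
})

test_that("null construction validates its inputs", {
  expect_error(build_null(numeric(0), n_x = 5, n_y = 5, seed = 1), "empty")
  expect_error(build_null(stats::runif(10), n_x = 5, n_y = 5, n_iter = 0,
                          pool_size = 10, seed = 1), "n_iter")
  expect_error(build_null(stats::runif(10), n_x = 5, n_y = 5,
                          quantile_level = 1.2, pool_size = 10, n_iter = 10,
                          seed = 1), "quantile_level")
  expect_error(build_null(stats::runif(10), n_x = 5, n_y = 5,
                          pool_size = 10, n_iter = 10, quantile_level = 0.9),
               "seed")
})

test_that("DWE calling respects the threshold, ordering, and size checks", {
  stats_dt <- data.table::data.table(
    edge_id = 1:4,
    M_x = c(0.5, 0.2, 0.9, 0.4), M_y = c(0.1, 0.3, 0.1, 0.4),
    omega_x = 0.1, omega_y = 0.1,
    s_xy = c(2, -0.5, 4, 0), S1 = c(2, 0.5, 4, 0),
    median_diff = c(0.4, -0.1, 0.8, 0), degenerate = FALSE)
  data.table::setattr(stats_dt, "n_x", 10L)
  data.table::setattr(stats_dt, "n_y", 10L)
  null <- structure(list(threshold = 1, n_x = 10L, n_y = 10L),
                    class = "ccnet_null")
  d <- call_dwes(stats_dt, null)
  expect_equal(d$edge_id, c(3L, 1L))          # sorted by |S1| descending
  expect_equal(d$direction, c(1, 1))
  # threshold above the max: empty set
  null$threshold <- 10
  expect_equal(nrow(call_dwes(stats_dt, null)), 0L)
  # threshold 0: everything strictly above comes back
  null$threshold <- 0
  expect_equal(nrow(call_dwes(stats_dt, null)), 3L)
  # degenerate edges are never called
  stats_dt$degenerate[3] <- TRUE
  expect_false(3L %in% call_dwes(stats_dt, null)$edge_id)
  # group size mismatch is an error
  null$n_x <- 99L
  expect_error(call_dwes(stats_dt, null), "group sizes")
})

test_that("contrast statistics carry group sizes and per-edge values", {
  set.seed(25)
  wt <- data.table::CJ(sample_id = sprintf("s%02d", 1:10), edge_id = 1:3)
  wt[, weight := stats::runif(.N)]
  groups <- data.table::data.table(sample_id = sprintf("s%02d", 1:10),
                                   group = rep(c("x", "y"), each = 5))
  st <- contrast_edges(wt, groups)
  expect_equal(nrow(st), 3L)
  expect_equal(attr(st, "n_x"), 5L)
  expect_equal(attr(st, "n_y"), 5L)
  for (e in 1:3) {
    x <- wt[edge_id == e & sample_id %in% groups[group == "x", sample_id], weight]
    y <- wt[edge_id == e & sample_id %in% groups[group == "y", sample_id], weight]
    expect_equal(st[edge_id == e, s_xy], naive_s1(x, y), tolerance = 1e-12)
  }
})
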