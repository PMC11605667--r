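# boundary-length geometry and the effort model

test_that("crack length matches brute-force edge enumeration", {
  empty <- matrix(FALSE, 5, 5)
  expect_equal(crack_length(empty), 0L)
  single <- empty; single[3, 3] <- TRUE
  expect_equal(crack_length(single), brute_crack_length(single))
  expect_equal(crack_length(single), 4L)
  square <- matrix(FALSE, 9, 9); square[4:6, 4:6] <- TRUE
  expect_equal(crack_length(square), brute_crack_length(square))
  expect_equal(crack_length(square), 12L)
  corner <- matrix(FALSE, 6, 6); corner[1:2, 1:2] <- TRUE
  expect_equal(crack_length(corner), brute_crack_length(corner))
  expect_equal(crack_length(corner), 8L)
  # random masks
  for (seed in 1:10) {
    m <- withr::with_seed(seed, matrix(runif(15 * 11) < 0.4, 15, 11))
    expect_equal(crack_length(m), brute_crack_length(m))
  }
})

test_that("shared crack length is symmetric and matches the pair enumerator", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[2, 1] <- TRUE; b[2, 2] <- TRUE
  expect_equal(shared_crack_length(a, b), 1L)
  far <- matrix(FALSE, 4, 4); far[4, 4] <- TRUE
  expect_equal(shared_crack_length(a, far), 0L)
  s1 <- matrix(FALSE, 6, 6); s1[2, 2:4] <- TRUE
  s2 <- matrix(FALSE, 6, 6); s2[3, 2:4] <- TRUE
  expect_equal(shared_crack_length(s1, s2), 3L)
  for (seed in 1:10) {
    lab <- random_label_map(9, 9, 3, seed)
    ma <- lab == 1; mb <- lab == 2
    expect_equal(shared_crack_length(ma, mb), brute_shared_length(ma, mb))
    expect_equal(shared_crack_length(ma, mb), shared_crack_length(mb, ma))
  }
  ov <- a; expect_error(shared_crack_length(a, ov), "overlap")
})

test_that("boundary conservation holds on random fully-labelled maps", {
  for (seed in 1:20) {
    C <- 4
    lab <- random_label_map(12, 12, C, seed)
    for (c in 0:(C - 1)) {
      m <- lab == c
      if (!any(m)) next
      shared <- sum(vapply(setdiff(0:(C - 1), c), function(cp)
        shared_crack_length(m, lab == cp), integer(1)))
      border <- sum(m[1, ]) + sum(m[nrow(m), ]) + sum(m[, 1]) + sum(m[, ncol(m)])
      expect_equal(crack_length(m), shared + border)
    }
  }
})

test_that("boundary statistics implement the prior-weighted running average", {
  fx <- make_fixture_suite()$halfplane  # each mask: 4x8 half, crack 24
  state <- annotation_state(rep(list(c(8, 8)), 4), fx$bounds, fx$catalog)
  m0 <- fx$gt$sections[[1]] == 0
  state <- apply_annotation(state, 1, 0, m0)
  stats <- update_boundary_stats(state, epsilon = 0.01)
  l <- crack_length(m0)
  expect_equal(stats$B["0", "0"], l / 1.01)
  # second annotation of the same class averages the two lengths
  state2 <- apply_annotation(state, 2, 0, m0)
  stats2 <- update_boundary_stats(state2, epsilon = 0.01)
  expect_equal(stats2$B["0", "0"], 2 * l / 2.01)
  # never co-annotated pair stays exactly zero
  expect_identical(stats2$B["0", "1"], 0)
  # co-annotation fills the off-diagonal symmetrically
  state3 <- apply_annotation(state2, 1, 1, fx$gt$sections[[1]] == 1)
  stats3 <- update_boundary_stats(state3, epsilon = 0.01)
  s <- shared_crack_length(m0, fx$gt$sections[[1]] == 1)
  expect_equal(stats3$B["0", "1"], s / 1.01)
  expect_identical(stats3$B, t(stats3$B))
})

test_that("direct-substitution cases of the boundary average hold", {
  # one annotation of length 40, eps = 0.01 -> 40 / 1.01
  expect_equal(40 / 1.01, 39.60396, tolerance = 1e-6)
  fx <- make_fixture_suite()$adversarial
  state <- annotation_state(rep(list(c(32, 32)), 2), fx$bounds, fx$catalog)
  m <- class_mask(fx$gt, 1, 1)
  state <- apply_annotation(state, 1, 1, m)
  stats <- update_boundary_stats(state)
  expect_equal(stats$B["1", "1"], crack_length(m) / 1.01)
})

test_that("remaining effort subtracts annotated neighbours and clamps at zero", {
  cat3 <- class_catalog(3)
  bounds <- weak_bounds(rep(1, 3), rep(4, 3), 4, cat3)
  state <- annotation_state(c(6, 6), bounds, cat3)
  stats <- structure(list(
    B = matrix(c(30, 4, 2, 4, 40, 10, 2, 10, 20), 3, 3,
               dimnames = list(0:2, 0:2)),
    count = c(1, 1, 1), pair_count = matrix(0, 3, 3), epsilon = 0.01),
    class = "boundary_stats")
  # nothing annotated in the section: full average
  expect_equal(remaining_effort(stats, state, 1, 1), 40)
  # class 0 and 2 annotated: subtract both shared averages
  m0 <- matrix(FALSE, 6, 6); m0[1, 1] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[6, 6] <- TRUE
  state2 <- apply_annotation(state, 1, 0, m0)
  state2 <- apply_annotation(state2, 1, 2, m2)
  expect_equal(remaining_effort(stats, state2, 1, 1), 40 - 4 - 10)
  # not compatible -> zero
  expect_equal(remaining_effort(stats, state2, 1, 0), 0)
  # clamping: inflate shared averages past the diagonal
  stats$B[2, 1] <- stats$B[1, 2] <- 50
  expect_equal(remaining_effort(stats, state2, 1, 1), 0)
})

test_that("remaining effort never increases as neighbours get annotated", {
  fx <- make_fixture_suite()$blobs
  state <- random_state(fx$gt, fx$bounds, 10, seed = 11)
  stats <- update_boundary_stats(state)
  pool <- candidate_pairs(state)
  i <- which(pool$n == pool$n[1])[1]
  n <- pool$n[i]
  before <- vapply(compatible_classes(state, n), function(c)
    remaining_effort(stats, state, n, c), numeric(1))
  c_new <- compatible_classes(state, n)[1]
  state2 <- apply_annotation(state, n, c_new, class_mask(fx$gt, n, c_new))
  after <- vapply(compatible_classes(state2, n), function(c)
    remaining_effort(stats, state2, n, c), numeric(1))
  keep <- setdiff(compatible_classes(state, n), c_new)
  expect_true(all(after <= before[match(keep, compatible_classes(state, n))] + 1e-12))
})

test_that("actual cost credits boundaries already traced by neighbours", {
  fx <- make_fixture_suite()$halfplane
  state <- annotation_state(rep(list(c(8, 8)), 4), fx$bounds, fx$catalog)
  m0 <- fx$gt$sections[[1]] == 0
  m1 <- fx$gt$sections[[1]] == 1
  full0 <- actual_annotation_cost(fx$gt, state, 1, 0)
  expect_equal(full0, crack_length(m0))
  state <- apply_annotation(state, 1, 0, m0)
  # the second class only pays for edges not already traced
  cost1 <- actual_annotation_cost(fx$gt, state, 1, 1)
  expect_equal(cost1, crack_length(m1) - shared_crack_length(m0, m1))
  expect_lt(cost1, crack_length(m1))
})

test_that("total cost counts each distinct edge once and is order-invariant", {
  # 4x4 split into two half-planes: 4 inter-class + 16 border edges
  cat2 <- class_catalog(2)
  lab <- matrix(rep(c(0L, 1L), each = 8), 4, 4)
  gt <- label_stack(list(lab), cat2)
  expect_equal(total_annotation_cost(gt), 20L)
  expect_equal(total_annotation_cost(gt), brute_total_edges(lab))
  # one-class stack: border edges only
  gt1 <- label_stack(list(matrix(0L, 5, 7)), cat2)
  expect_equal(total_annotation_cost(gt1), 2L * (5L + 7L))
  # random maps agree with the distinct-edge enumerator
  for (seed in 1:5) {
    labr <- random_label_map(10, 8, 4, seed)
    gtr <- label_stack(list(labr), class_catalog(4))
    expect_equal(total_annotation_cost(gtr), brute_total_edges(labr))
  }
})

test_that("charging every pair in random orders always sums to the total", {
  fx <- make_fixture_suite()$halfplane
  total <- total_annotation_cost(fx$gt)
  for (seed in 1:10) {
    state <- annotation_state(rep(list(c(8, 8)), 4), fx$bounds, fx$catalog)
    pool <- candidate_pairs(state)
    order <- withr::with_seed(seed, sample.int(nrow(pool)))
    cum <- 0L
    for (i in order) {
      cum <- cum + actual_annotation_cost(fx$gt, state, pool$n[i], pool$c[i])
      state <- apply_annotation(state, pool$n[i], pool$c[i],
                                class_mask(fx$gt, pool$n[i], pool$c[i]))
    }
    expect_identical(cum, total)
  }
})

test_that("boundary statistics and effort tables serialize faithfully", {
  fx <- make_fixture_suite()$halfplane
  state <- random_state(fx$gt, fx$bounds, 4, seed = 8)
  stats <- update_boundary_stats(state)
  f <- withr::local_tempfile(fileext = ".json")
  save_boundary_stats(stats, f)
  back <- load_boundary_stats(f)
  expect_equal(back$B, stats$B)
  expect_equal(back$count, stats$count)
  expect_equal(back$epsilon, stats$epsilon)
  R <- effort_table(stats, state)
  fc <- withr::local_tempfile(fileext = ".csv")
  save_effort_table(R, fc)
  df <- utils::read.csv(fc)
  expect_equal(nrow(df), 4)
  expect_equal(unname(as.matrix(df[, -1])), unname(R))
})
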