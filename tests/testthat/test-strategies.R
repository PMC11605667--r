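# Dice tracking, the smoothed predictor, and query selection

test_that("the Dice coefficient handles the degenerate mask cases", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  none <- matrix(FALSE, 2, 2)
  expect_equal(dice_coefficient(none, none), 1)
  expect_equal(dice_coefficient(a, none), 0)
  # |P| = |R| = 4, overlap 2 -> 0.5
  p <- matrix(FALSE, 2, 4); p[, 1:2] <- TRUE
  r <- matrix(FALSE, 2, 4); r[, 2:3] <- TRUE
  expect_equal(dice_coefficient(p, r), 0.5)
})

test_that("the smoothed Dice predictor mixes the last two observations", {
  h <- matrix(c(0.8, 0.6), ncol = 1, dimnames = list(NULL, "1"))
  expect_equal(predict_dice(h, 1, alpha = 0.5), 0.7)
  expect_equal(predict_dice(h, 1, alpha = 1), 0.6)
  expect_equal(predict_dice(h, 1, alpha = 0), 0.8)
  # bootstrap: a single record counts for both terms
  h1 <- matrix(0.4, ncol = 1, dimnames = list(NULL, "1"))
  expect_equal(predict_dice(h1, 1, alpha = 0.3), 0.4)
  expect_error(predict_dice(h1[0, , drop = FALSE], 1), "empty")
})

test_that("the candidate pool tracks bounds and annotations", {
  fx <- make_fixture_suite()$blobs
  state <- annotation_state(lapply(fx$gt$sections, dim), fx$bounds, fx$catalog)
  pool <- candidate_pairs(state)
  expected <- sum(fx$bounds$last - fx$bounds$first + 1L)
  expect_equal(nrow(pool), expected)
  # out-of-bounds pairs never appear
  expect_true(all(fx$bounds$first[as.character(pool$c)] <= pool$n &
                    pool$n <= fx$bounds$last[as.character(pool$c)]))
  # bootstrap shrinks the pool by exactly C
  oracle <- oracle_annotator(fx$gt)
  st2 <- withr::with_seed(1, init_annotations(oracle, fx$bounds))
  expect_equal(nrow(candidate_pairs(st2)), expected - 6L)
})

test_that("a fully annotated stack yields an empty pool", {
  fx <- make_fixture_suite()$halfplane
  state <- annotation_state(rep(list(c(8, 8)), 4), fx$bounds, fx$catalog)
  pool <- candidate_pairs(state)
  for (i in seq_len(nrow(pool))) {
    state <- apply_annotation(state, pool$n[i], pool$c[i],
                              class_mask(fx$gt, pool$n[i], pool$c[i]))
  }
  expect_equal(nrow(candidate_pairs(state)), 0L)
})

test_that("strategy scores implement the stated formulas", {
  pool <- tibble::tibble(n = c(1L, 2L), c = c(1L, 2L))
  R <- matrix(10, 2, 3, dimnames = list(NULL, 0:2))
  H <- matrix(0, 2, 3, dimnames = list(NULL, 0:2))
  H[1, "1"] <- 0.2; H[2, "2"] <- 0.4
  dt <- c("0" = 0.9, "1" = 0.7, "2" = 0.5)
  s_bd <- score_candidates("BDalpha", pool, dt, R)
  expect_equal(s_bd$score, c(0.3 / 10, 0.5 / 10))
  expect_equal(select_query(s_bd), list(n = 2L, c = 2L))
  s_hb <- score_candidates("HB", pool, dt, R, H)
  expect_equal(s_hb$score, c(0.2 / 10, 0.4 / 10))
  s_hbd <- score_candidates("HBDalpha", pool, dt, R, H)
  expect_equal(s_hbd$score, c(0.3 * 0.2 / 10, 0.5 * 0.4 / 10))
  s_hd <- score_candidates("HDalpha", pool, dt, entropy = H)
  expect_equal(s_hd$score, c(0.3 * 0.2, 0.5 * 0.4))
  s_h <- score_candidates("H", pool, dt, entropy = H)
  expect_equal(s_h$score, c(0.2, 0.4))
  # zero remaining effort scores +Inf and is taken first
  R2 <- R; R2[2, 3] <- 0
  s0 <- score_candidates("BDalpha", pool, dt, R2)
  expect_equal(s0$score[2], Inf)
  expect_equal(select_query(s0), list(n = 2L, c = 2L))
  expect_error(score_candidates("nope", pool, dt, R), "unknown strategy")
  expect_error(score_candidates("rand", pool, dt, R), "not score-based")
})

test_that("select_query matches the exhaustive argmax on random score tables", {
  for (seed in 1:200) {
    scores <- withr::with_seed(seed, {
      k <- sample(2:12, 1)
      tibble::tibble(
        n = sample(1:6, k, replace = TRUE),
        c = sample(0:4, k, replace = TRUE),
        # coarse grid of values so ties actually occur
        score = sample(seq(0, 1, by = 0.25), k, replace = TRUE),
        dtilde = sample(seq(0, 1, by = 0.5), k, replace = TRUE))
    })
    expect_identical(select_query(scores), brute_select(scores))
  }
})

test_that("ties break by room for improvement, then class, then section", {
  scores <- tibble::tibble(n = c(2L, 1L), c = c(1L, 1L),
                           score = c(0.5, 0.5), dtilde = c(0.2, 0.4))
  expect_equal(select_query(scores)$n, 2L)  # larger 1 - dtilde wins
  all_eq <- tibble::tibble(n = c(3L, 1L, 2L), c = c(2L, 1L, 1L),
                           score = 1, dtilde = 0.5)
  expect_equal(select_query(all_eq), list(n = 1L, c = 1L))
})

test_that("BDalpha selection is invariant to a global rescaling of the efforts", {
  for (seed in 1:20) {
    pool <- tibble::tibble(n = rep(1:4, each = 3), c = rep(0:2, 4))
    R <- withr::with_seed(seed, matrix(runif(12, 0.5, 30), 4, 3,
                                       dimnames = list(NULL, 0:2)))
    dt <- withr::with_seed(seed + 1,
                           stats::setNames(runif(3), as.character(0:2)))
    pick1 <- select_query(score_candidates("BDalpha", pool, dt, R))
    pick2 <- select_query(score_candidates("BDalpha", pool, dt, 2 * R))
    expect_identical(pick1, pick2)
  }
})

test_that("the uniform baseline finishes a section then minimises the largest gap", {
  fx <- make_fixture_suite()$blobs
  # half-finished current section: stay in it
  state <- annotation_state(lapply(fx$gt$sections, dim), fx$bounds, fx$catalog)
  state <- apply_annotation(state, 6, 0, class_mask(fx$gt, 6, 0))
  q <- withr::with_seed(1, select_uniform(state, current_section = 6))
  expect_equal(q$n, 6L)
  # no current section: chosen section must minimise the max uncovered run
  for (seed in 1:100) {
    st <- random_state(fx$gt, fx$bounds, sample(0:8, 1), seed)
    q <- withr::with_seed(seed + 500, select_uniform(st))
    covered <- rowSums(st$A) > 0
    cand <- which(vapply(1:12, function(n)
      length(compatible_classes(st, n)) > 0, logical(1)))
    gaps <- vapply(cand, function(n) {
      cv <- covered; cv[n] <- TRUE; brute_max_gap(cv)
    }, integer(1))
    expect_true(q$n %in% cand[gaps == min(gaps)])
    expect_true(q$c %in% compatible_classes(st, q$n))
  }
})

test_that("random selection is uniform over the pool and seed-stable", {
  fx <- make_fixture_suite()$halfplane
  state <- annotation_state(rep(list(c(8, 8)), 4), fx$bounds, fx$catalog)
  pool <- candidate_pairs(state)  # 8 pairs
  draws <- withr::with_seed(123, vapply(1:4000, function(i) {
    q <- select_random(state)
    paste(q$n, q$c)
  }, character(1)))
  counts <- table(factor(draws, levels = paste(pool$n, pool$c)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  a <- withr::with_seed(7, select_random(state))
  b <- withr::with_seed(7, select_random(state))
  expect_identical(a, b)
})
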