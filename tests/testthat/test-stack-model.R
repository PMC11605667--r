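# data model and I/O for stacks, bounds and annotation state

test_that("image stacks load from a directory of PNGs and rescale to [0,1]", {
  dir <- withr::local_tempdir()
  withr::with_seed(1, {
    for (k in 1:3) {
      png::writePNG(matrix(runif(48, 0.2, 0.8), 6, 8),
                    file.path(dir, sprintf("s%02d.png", k)))
    }
  })
  st <- load_image_stack(dir)
  expect_equal(st$n_sections, 3)
  for (s in st$sections) {
    expect_equal(range(s), c(0, 1))
    expect_equal(dim(s), c(6, 8))
  }
})

test_that("multi-page TIFF stacks load with order preserved", {
  f <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:5, function(k) matrix(k / 10, 4, 4) + diag(4) * 0.05)
  tiff::writeTIFF(pages, f, bits.per.sample = 16L)
  st <- load_image_stack(f)
  expect_equal(st$n_sections, 5)
})

test_that("constant sections rescale to all zeros and bad paths error", {
  st <- image_stack(list(matrix(0.7, 4, 4)))
  expect_true(all(st$sections[[1]] == 0))
  expect_error(load_image_stack(file.path(tempdir(), "no-such-dir-xyz")),
               "no such path")
  empty <- withr::local_tempdir()
  expect_error(load_image_stack(empty), "no PNG/TIFF")
})

test_that("label stacks validate against the catalog, naming the offender", {
  cat3 <- class_catalog(3)
  ok <- label_stack(list(matrix(c(0L, 1L, 2L, 0L), 2, 2)), cat3)
  expect_s3_class(ok, "label_stack")
  expect_error(label_stack(list(matrix(0L, 2, 2), matrix(7L, 2, 2)), cat3),
               "section 2.*7")
  # a class absent everywhere is fine at the container level
  expect_silent(label_stack(list(matrix(0L, 2, 2)), cat3))
})

test_that("label stacks round-trip through indexed multi-page TIFF", {
  cat3 <- class_catalog(3)
  secs <- lapply(1:3, function(k) random_label_map(6, 7, 3, seed = k))
  gt <- label_stack(secs, cat3)
  f <- withr::local_tempfile(fileext = ".tif")
  save_label_stack(gt, f)
  back <- load_label_stack(f, cat3)
  expect_identical(back$sections, gt$sections)
})

test_that("weak bounds clamp the safety margin and pin the background", {
  cat3 <- class_catalog(3)
  b <- weak_bounds(c(1, 3, 5), c(10, 6, 8), 10, cat3, safety_margin = 2)
  expect_equal(unname(b$first), c(1, 1, 3))
  expect_equal(unname(b$last), c(10, 8, 10))
  expect_error(weak_bounds(c(1, 5, 2), c(10, 4, 3), 10, cat3), "bounds")
})

test_that("compatible classes follow bounds and annotations", {
  cat3 <- class_catalog(3)
  bounds <- weak_bounds(c(1, 3, 1), c(8, 6, 8), 8, cat3)
  state <- annotation_state(c(4, 4), bounds, cat3)
  expect_equal(compatible_classes(state, 4), c(0L, 1L, 2L))
  expect_equal(compatible_classes(state, 7), c(0L, 2L))  # class 1 out of bounds
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  state <- apply_annotation(state, 4, 1, mask)
  expect_equal(compatible_classes(state, 4), c(0L, 2L))
  expect_error(compatible_classes(state, 9), "out of range")
})

test_that("annotations update A, respect disjointness, and flag implication", {
  cat3 <- class_catalog(3)
  bounds <- weak_bounds(c(1, 1, 1), c(2, 2, 2), 2, cat3)
  state <- annotation_state(c(3, 3), bounds, cat3)
  m1 <- matrix(FALSE, 3, 3); m1[1, ] <- TRUE
  state <- apply_annotation(state, 1, 1, m1)
  expect_equal(unname(state$A[1, "1"]), 1L)
  expect_error(apply_annotation(state, 1, 1, m1), "already annotated")
  overlap <- matrix(FALSE, 3, 3); overlap[1, 2] <- TRUE
  expect_error(apply_annotation(state, 1, 2, overlap), "overlaps")
  # annotating all but one class sets the implication flag
  m2 <- matrix(FALSE, 3, 3); m2[2, ] <- TRUE
  state <- apply_annotation(state, 1, 2, m2)
  expect_true(state$implied[1])
  expect_false(state$implied[2])
})

test_that("bootstrap requires one annotation per class and bounds compliance", {
  cat2 <- class_catalog(2)
  bounds <- weak_bounds(c(1, 2), c(3, 3), 3, cat2)
  full <- matrix(TRUE, 2, 2); none <- matrix(FALSE, 2, 2)
  expect_error(
    build_initial_state(list(list(n = 1, c = 0, mask = full)),
                        c(2, 2), bounds, cat2),
    "missing: 1")
  # class 1 annotated outside its bounds is rejected
  expect_error(
    build_initial_state(list(list(n = 1, c = 1, mask = full)),
                        c(2, 2), bounds, cat2),
    "not compatible")
  st <- build_initial_state(
    list(list(n = 1, c = 0, mask = full), list(n = 2, c = 1, mask = full)),
    c(2, 2), bounds, cat2)
  expect_equal(sum(st$A), 2L)
})

test_that("Ln and Un partition every section after random annotation runs", {
  fx <- make_fixture_suite()$halfplane
  for (seed in 1:5) {
    state <- random_state(fx$gt, fx$bounds, 6, seed)
    for (n in seq_len(state$n_sections)) {
      lab <- state$labels[[n]]
      # Ln: labelled with a valid id; Un: NA. union is the whole domain
      expect_true(all(is.na(lab) | lab %in% fx$catalog$class_ids))
      # incremental Cn equals Cn recomputed from scratch from A and bounds
      ids <- fx$catalog$class_ids
      scratch <- sort(ids[fx$bounds$first <= n & n <= fx$bounds$last &
                            state$A[n, ] == 0L])
      expect_identical(compatible_classes(state, n), scratch)
      # every annotated mask pixel carries exactly its class label
      for (c in ids[state$A[n, ] == 1L]) {
        m <- annotated_mask(state, n, c)
        expect_true(all(lab[m] == c))
      }
    }
  }
})

test_that("annotation state round-trips bit-exactly through disk", {
  fx <- make_fixture_suite()$halfplane
  state <- random_state(fx$gt, fx$bounds, 5, seed = 3)
  dir <- withr::local_tempdir()
  save_state(state, dir)
  back <- load_state(dir)
  expect_identical(unname(back$A), unname(state$A))
  expect_identical(back$labels, state$labels)
  expect_identical(unname(back$bounds$first), unname(state$bounds$first))
  expect_identical(unname(back$bounds$last), unname(state$bounds$last))
  expect_identical(back$implied, state$implied)
})

test_that("query logs round-trip with the fixed CSV header", {
  log <- tibble::tibble(t = 1:2, section = c(3L, 1L), class = c(0L, 2L),
                        cost = c(12L, 5L), cumulative_cost = c(12L, 17L),
                        mean_dice = c(0.5, 0.75))
  f <- withr::local_tempfile(fileext = ".csv")
  save_log(log, f)
  expect_identical(readLines(f, n = 1),
                   "t,section,class,cost,cumulative_cost,mean_dice")
  expect_equal(as.data.frame(load_log(f)), as.data.frame(log))
  empty <- log[0, ]
  save_log(empty, f)
  expect_identical(readLines(f), "t,section,class,cost,cumulative_cost,mean_dice")
})
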