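# brute-force reference implementations used as independent oracles.

# enumerate every cut edge of a binary mask: loop over all 4-adjacent
# pixel pairs plus the image-border edges of mask pixels
brute_crack_length <- function(mask) {
  m <- as.matrix(mask) != 0
  H <- nrow(m); W <- ncol(m)
  n <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!m[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > H || jj < 1 || jj > W) n <- n + 1L  # border edge
        else if (!m[ii, jj]) n <- n + 1L
      }
    }
  }
  n
}

# enumerate unordered 4-adjacent pairs with one pixel in each mask
brute_shared_length <- function(a, b) {
  a <- as.matrix(a) != 0; b <- as.matrix(b) != 0
  H <- nrow(a); W <- ncol(a)
  n <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!a[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && b[ii, jj]) n <- n + 1L
      }
    }
  }
  n
}

# distinct cut edges of a full label map: inter-class edges once each,
# border edges once per border pixel side
brute_total_edges <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  n <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (i < H && lab[i, j] != lab[i + 1, j]) n <- n + 1L
      if (j < W && lab[i, j] != lab[i, j + 1]) n <- n + 1L
    }
  }
  n + 2L * (H + W)
}

# exhaustive argmax with the package's tie-breaking rules
brute_select <- function(scores) {
  best <- NULL
  for (i in seq_len(nrow(scores))) {
    if (is.null(best)) { best <- i; next }
    a <- scores[i, ]; b <- scores[best, ]
    better <- (a$score > b$score) ||
      (a$score == b$score && a$dtilde < b$dtilde) ||
      (a$score == b$score && a$dtilde == b$dtilde && a$c < b$c) ||
      (a$score == b$score && a$dtilde == b$dtilde && a$c == b$c && a$n < b$n)
    if (better) best <- i
  }
  list(n = scores$n[best], c = scores$c[best])
}

# max run of consecutive sections with no annotation, given covered flags
brute_max_gap <- function(covered) {
  runs <- rle(!covered)
  gaps <- runs$lengths[runs$values]
  if (length(gaps) == 0L) 0L else max(gaps)
}

# random partial annotation state over a small ground truth
random_state <- function(gt, bounds, n_annotations, seed) {
  state <- annotation_state(lapply(gt$sections, dim), bounds, gt$catalog)
  withr::with_seed(seed, {
    for (k in seq_len(n_annotations)) {
      pool <- candidate_pairs(state)
      if (nrow(pool) == 0L) break
      i <- sample.int(nrow(pool), 1L)
      state <- apply_annotation(state, pool$n[i], pool$c[i],
                                class_mask(gt, pool$n[i], pool$c[i]))
    }
  })
  state
}

# small random multi-class label map (every pixel labelled)
random_label_map <- function(H, W, C, seed) {
  withr::with_seed(seed, {
    centers <- cbind(runif(C, 1, H), runif(C, 1, W))
    lab <- matrix(0L, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      d <- (centers[, 1] - i)^2 + (centers[, 2] - j)^2
      lab[i, j] <- which.min(d) - 1L
    }
    lab
  })
}

random_probs <- function(H, W, C, seed) {
  withr::with_seed(seed, {
    p <- array(runif(H * W * C, 0.05, 1), dim = c(H, W, C))
    s <- apply(p, c(1, 2), sum)
    p / array(rep(s, C), dim = dim(p))
  })
}

tiny_state <- function(seed = 1, n_annotations = 3) {
  fx <- make_fixture_suite()$halfplane
  list(fx = fx,
       state = random_state(fx$gt, fx$bounds, n_annotations, seed))
}
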