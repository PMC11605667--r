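# synthetic coronal-section stacks and the simulated (oracle) annotator.
#
# a procedural multi-class base label map (adjacent blobs grown from
# seeded centroids) is restricted per section to the classes whose support
# interval contains the section, then deformed with an independent
# similarity + nonlinear field per section; intensities are rendered as
# class mean + smooth bias field + Gaussian noise. weak bounds equal the
# configured supports by construction.

#' Synthetic stack configuration
#'
#' @param n_sections stack length N, default 12.
#' @param height,width section size, default 64 x 64.
#' @param n_classes total classes C (background + C-1 blobs), default 6.
#' @param supports list of `c(first, last)` per class (class-id order).
#'   Default: background spans the stack; foreground classes get staggered
#'   contiguous intervals of two thirds of the stack.
#' @param rot_sd,trans_sd,logscale_sd similarity deformation sds per
#'   section: 10 degrees, 10 pixels, 0.1 log-scale.
#' @param warp_sd,warp_spacing nonlinear field: Gaussian control-point
#'   shifts (sd 4 px) on a 5-px grid.
#' @param means per-class intensity means (pairwise distinct). Default
#'   evenly spaced in \[0.12, 0.92\].
#' @param noise_sd intensity noise sd, default 0.02.
#' @param bias_amp amplitude (sd) of the smooth bias field, default 0.015.
#' @param seed master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sections = 12L, height = 64L, width = 64L,
                             n_classes = 6L, supports = NULL,
                             rot_sd = 10, trans_sd = 10, logscale_sd = 0.1,
                             warp_sd = 4, warp_spacing = 5,
                             means = NULL, noise_sd = 0.02, bias_amp = 0.015,
                             seed = 1L) {
  N <- as.integer(n_sections)
  C <- as.integer(n_classes)
  if (is.null(supports)) {
    len <- max(1L, ceiling(2 * N / 3))
    starts <- round(seq(1, N - len + 1, length.out = max(C - 1L, 1L)))
    supports <- c(list(c(1L, N)),
                  lapply(starts, function(s) c(s, min(N, s + len - 1L))))
  }
  if (length(supports) != C) stop("need one support interval per class")
  supports[[1]] <- c(1L, N)  # background spans the stack
  for (s in supports) {
    if (s[1] < 1L || s[2] > N || s[1] > s[2])
      stop("supports must be contiguous intervals within the stack")
  }
  if (is.null(means)) means <- seq(0.12, 0.92, length.out = C)
  if (anyDuplicated(round(means, 10))) stop("class means must be distinct")
  structure(list(n_sections = N, height = as.integer(height),
                 width = as.integer(width), n_classes = C,
                 supports = supports, rot_sd = rot_sd, trans_sd = trans_sd,
                 logscale_sd = logscale_sd, warp_sd = warp_sd,
                 warp_spacing = warp_spacing, means = means,
                 noise_sd = noise_sd, bias_amp = bias_amp,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# base label map: foreground blobs on a ring around the centre, label =
# nearest (radius-scaled) centroid among the eligible classes, background
# elsewhere. returns the scaled-distance array so per-section restriction
# just re-runs the argmin over eligible classes.
base_distance_maps <- function(config) {
  H <- config$height; W <- config$width
  K <- config$n_classes - 1L
  ang <- 2 * pi * (seq_len(K) - 1) / K
  rad <- 0.26 * min(H, W)
  ctr_r <- (H + 1) / 2 + rad * sin(ang)
  ctr_c <- (W + 1) / 2 + rad * cos(ang)
  blob_r <- (0.14 + 0.08 * ((seq_len(K) - 1) %% 3) / 2) * min(H, W)
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  d <- array(0, dim = c(H, W, K))
  for (k in seq_len(K)) {
    d[, , k] <- matrix(sqrt((rr - ctr_r[k])^2 + (cc - ctr_c[k])^2) / blob_r[k],
                       H, W)
  }
  d
}

section_base_labels <- function(dmaps, eligible_fg) {
  H <- dim(dmaps)[1]; W <- dim(dmaps)[2]
  lab <- matrix(0L, H, W)
  if (length(eligible_fg) == 0L) return(lab)
  D <- matrix(dmaps[, , eligible_fg, drop = FALSE],
              ncol = length(eligible_fg))
  k <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(H * W), k)]
  lab[dmin < 1] <- eligible_fg[k[dmin < 1]]
  lab
}

#' Generate a synthetic image stack with ground truth and weak bounds
#'
#' Deterministic given `config$seed`. Each section deforms the base label
#' map (restricted to its eligible classes) with an independent similarity
#' transform (rotation/translation/log-scale drawn from zero-mean
#' Gaussians) composed with a nonlinear control-grid field, then renders
#' intensities as class mean + smooth bias field + Gaussian noise, clipped
#' to \[0, 1\]. A section's deformation is redrawn (deterministically) in
#' the rare case it pushes an eligible class out of frame, so every class
#' is present in exactly its configured support.
#'
#' @param config a [synthetic_config()].
#' @return `list(stack, gt, bounds, catalog)`.
#' @export
generate_synthetic_stack <- function(config = synthetic_config()) {
  catalog <- class_catalog(config$n_classes)
  dmaps <- base_distance_maps(config)
  if (all(section_base_labels(dmaps, seq_len(config$n_classes - 1L)) == 0L))
    stop("degenerate configuration: no foreground area")
  N <- config$n_sections
  labels <- vector("list", N)
  images <- vector("list", N)
  for (n in seq_len(N)) {
    eligible <- which(vapply(config$supports[-1], function(s)
      s[1] <= n && n <= s[2], logical(1)))
    base <- section_base_labels(dmaps, eligible)
    for (retry in 0:25) {
      lab <- with_seed(config$seed + 1009L * n + 101L * retry, {
        rot <- stats::rnorm(1, sd = config$rot_sd)
        trans <- stats::rnorm(2, sd = config$trans_sd)
        sc <- exp(stats::rnorm(1, sd = config$logscale_sd))
        field <- random_displacement_field(config$height, config$width,
                                           config$warp_sd, config$warp_spacing)
        warp_section(base * 1, base, rotation = rot, translation = trans,
                     scale = sc, field = field)$labels
      })
      if (all(eligible %in% lab)) break
    }
    if (!all(eligible %in% lab))
      stop(sprintf("could not keep all classes in frame for section %d", n))
    labels[[n]] <- lab
    images[[n]] <- with_seed(config$seed + 7919L * n, {
      bias <- random_displacement_field(config$height, config$width,
                                        config$bias_amp,
                                        max(config$height, config$width) / 3)$dr
      img <- matrix(config$means[lab + 1L], config$height, config$width) +
        bias + matrix(stats::rnorm(length(lab), sd = config$noise_sd),
                      config$height, config$width)
      pmin(pmax(img, 0), 1)
    })
  }
  gt <- label_stack(labels, catalog)
  first <- vapply(config$supports, function(s) as.integer(s[1]), integer(1))
  last <- vapply(config$supports, function(s) as.integer(s[2]), integer(1))
  bounds <- weak_bounds(first, last, N, catalog)
  list(stack = image_stack(images, rescale = FALSE), gt = gt,
       bounds = bounds, catalog = catalog)
}

#' Extract weak bounds from a complete ground truth
#'
#' First/last section where each class has any pixel, widened by a safety
#' margin and clipped to the stack; background is always the full stack.
#'
#' @param gt a complete [label_stack()].
#' @param margin safety margin in sections, default 0.
#' @return A [weak_bounds()].
#' @export
extract_weak_bounds <- function(gt, margin = 0L) {
  ids <- gt$catalog$class_ids
  present <- vapply(gt$sections, function(s) ids %in% s, logical(length(ids)))
  present <- matrix(present, nrow = length(ids))
  first <- last <- integer(length(ids))
  for (j in seq_along(ids)) {
    w <- which(present[j, ])
    if (length(w) == 0L && ids[j] != gt$catalog$background_id)
      stop(sprintf("class %d is absent from every section", ids[j]))
    if (length(w) == 0L) w <- seq_len(gt$n_sections)
    first[j] <- min(w); last[j] <- max(w)
  }
  weak_bounds(first, last, gt$n_sections, gt$catalog, safety_margin = margin)
}

#' Simulated annotator
#'
#' Answers queries with exact ground-truth masks and picks the bootstrap
#' sections: for each class, the central section of its presence interval
#' shifted by a uniform draw within `window` sections (clipped).
#'
#' @param gt ground-truth [label_stack()].
#' @param window half-width of the central-section draw, default 3.
#' @return An `oracle_annotator`.
#' @export
oracle_annotator <- function(gt, window = 3L) {
  structure(list(gt = gt, window = as.integer(window)),
            class = "oracle_annotator")
}

#' Answer one query with the ground-truth mask
#' @param oracle an [oracle_annotator()]. @param n section. @param c class id.
#' @return logical mask (possibly empty inside a safety margin).
#' @export
answer_query <- function(oracle, n, c) class_mask(oracle$gt, n, c)

#' Bootstrap annotations: one near-central section per class
#'
#' For every class (in id order) annotates the ground-truth mask on the
#' central section of its presence interval, shifted by a uniform integer
#' draw in `[-window, window]` clipped to the interval; sections where the
#' class happens to be empty are skipped by scanning outward. Draws come
#' from the current RNG stream.
#'
#' @param oracle an [oracle_annotator()].
#' @param bounds a [weak_bounds()].
#' @return An [annotation_state()] with exactly C annotations.
#' @export
init_annotations <- function(oracle, bounds) {
  gt <- oracle$gt
  catalog <- gt$catalog
  dims <- lapply(gt$sections, dim)
  masks <- list()
  for (c in catalog$class_ids) {
    present <- which(vapply(gt$sections, function(s) c %in% s, logical(1)))
    if (c == catalog$background_id && length(present) == 0L)
      present <- seq_len(gt$n_sections)
    lo <- min(present); hi <- max(present)
    centre <- floor((lo + hi) / 2)
    n <- centre + sample.int(2L * oracle$window + 1L, 1L) - oracle$window - 1L
    n <- min(max(n, lo), hi)
    if (!any(class_mask(gt, n, c)) && c != catalog$background_id) {
      # class absent at the drawn section: scan outward for the nearest
      # section where it is present
      n <- present[which.min(abs(present - n))]
    }
    masks[[length(masks) + 1L]] <- list(n = n, c = c, mask = class_mask(gt, n, c))
  }
  build_initial_state(masks, dims, bounds, catalog)
}

#' Deterministic fixture suite
#'
#' Three tiny named stacks used throughout the tests and examples:
#' \itemize{
#'   \item `halfplane`: 4 sections of 8 x 8, two classes split left/right,
#'     near-noiseless intensities.
#'   \item `blobs`: the default [synthetic_config()] stack (12 sections,
#'     64 x 64, 6 classes, separable intensity means).
#'   \item `adversarial`: one compact square and one comb-shaped class of
#'     equal pixel area, probing the boundary-length effort premise
#'     (convoluted structures cost more tracing than compact ones).
#' }
#'
#' @return named list; each element has `stack`, `gt`, `bounds`, `catalog`.
#' @export
make_fixture_suite <- function() {
  # (a) half-plane
  cat2 <- class_catalog(2L)
  lab_a <- matrix(rep(c(0L, 1L), each = 4 * 8), nrow = 8)  # cols 1:4 = 0
  gt_a <- label_stack(rep(list(lab_a), 4), cat2)
  img_a <- with_seed(42L, lapply(1:4, function(n)
    pmin(pmax(0.25 + 0.5 * lab_a +
                matrix(stats::rnorm(64, sd = 0.02), 8, 8), 0), 1)))
  halfplane <- list(stack = image_stack(img_a, rescale = FALSE), gt = gt_a,
                    bounds = extract_weak_bounds(gt_a), catalog = cat2)

  # (b) synthetic blob stack
  blobs <- generate_synthetic_stack(synthetic_config(seed = 7L))

  # (c) equal-area compact vs convoluted classes
  cat3 <- class_catalog(3L)
  lab_c <- matrix(0L, 32, 32)
  lab_c[5:12, 5:12] <- 1L                      # compact 8x8 square, 64 px
  for (col in seq(5, 19, by = 2)) lab_c[20:27, col] <- 2L  # 8 teeth, 64 px
  gt_c <- label_stack(rep(list(lab_c), 2), cat3)
  means_c <- c(0.1, 0.5, 0.9)
  img_c <- with_seed(43L, lapply(1:2, function(n)
    pmin(pmax(matrix(means_c[lab_c + 1L], 32, 32) +
                matrix(stats::rnorm(1024, sd = 0.02), 32, 32), 0), 1)))
  adversarial <- list(stack = image_stack(img_c, rescale = FALSE), gt = gt_c,
                      bounds = extract_weak_bounds(gt_c), catalog = cat3)

  list(halfplane = halfplane, blobs = blobs, adversarial = adversarial)
}
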