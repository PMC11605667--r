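# geometric + intensity augmentation and the shared image warper.
#
# a warp is defined by a similarity/affine map about the image centre plus
# a dense per-pixel displacement field; output pixels are inverse-mapped
# into the input and sampled bilinearly (intensities) or nearest-neighbour
# (labels, NA-preserving). coordinates are clamped at the image edge.

#' Augmentation configuration
#'
#' Uniform ranges for the similarity/photometric parameters and the
#' nonlinear-field parameters: rotation and shear in degrees, translation
#' in pixels, scale as a factor (sampled uniformly in the log domain),
#' brightness on the \[0, 255\] scale, contrast as a factor; the nonlinear
#' field draws i.i.d. Gaussian (x, y) shifts (sd `warp_sd` pixels) at
#' control points on a regular grid (`warp_spacing` pixels) and bilinearly
#' upsamples them to a dense field.
#'
#' @param rotation,translation,scale,shear,brightness,contrast length-2
#'   `c(min, max)` ranges.
#' @param warp_sd control-point displacement sd (pixels), default 4.
#' @param warp_spacing control-grid spacing (pixels), default 5.
#' @param crop random-crop side (pixels), default 128.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation = c(-10, 10), translation = c(-10, 10),
                                scale = c(0.8, 1.2), shear = c(-10, 10),
                                brightness = c(-20, 20), contrast = c(0.8, 1.25),
                                warp_sd = 4, warp_spacing = 5, crop = 128L) {
  cfg <- list(rotation = rotation, translation = translation, scale = scale,
              shear = shear, brightness = brightness, contrast = contrast,
              warp_sd = warp_sd, warp_spacing = warp_spacing,
              crop = as.integer(crop))
  for (r in cfg[c("rotation", "translation", "scale", "shear", "brightness",
                  "contrast")]) {
    if (r[1] > r[2]) stop("augmentation range must satisfy min <= max")
  }
  structure(cfg, class = "augmentation_config")
}

# bilinear sample of matrix m at (row, col) coordinate vectors (clamped)
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  if (H == 1L) r0 <- rep(1, length(r))
  if (W == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

nearest_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(round(r), 1), H)
  c <- pmin(pmax(round(c), 1), W)
  m[cbind(r, c)]
}

# Gaussian control-point displacement field, bilinearly upsampled.
# draws from the current RNG stream; returns list(dr, dc) H x W matrices.
random_displacement_field <- function(H, W, sd, spacing) {
  gr <- ceiling((H - 1) / spacing) + 1L
  gc <- ceiling((W - 1) / spacing) + 1L
  ctrl_r <- matrix(stats::rnorm(gr * gc, sd = sd), gr, gc)
  ctrl_c <- matrix(stats::rnorm(gr * gc, sd = sd), gr, gc)
  rr <- rep((seq_len(H) - 1) / spacing + 1, times = W)
  cc <- rep((seq_len(W) - 1) / spacing + 1, each = H)
  list(dr = matrix(bilinear_sample(ctrl_r, rr, cc), H, W),
       dc = matrix(bilinear_sample(ctrl_c, rr, cc), H, W))
}

#' Warp a section (and optionally its labels)
#'
#' Applies a similarity/affine transform about the image centre composed
#' with a dense displacement field. Output pixels are inverse-mapped:
#' intensities are sampled bilinearly, labels nearest-neighbour (`NA`
#' preserved). All-neutral parameters with a zero field reproduce the
#' input exactly.
#'
#' @param image numeric matrix.
#' @param labels optional integer matrix (may contain `NA`).
#' @param rotation degrees. @param translation length-2 (rows, cols) pixels.
#' @param scale factor. @param shear degrees.
#' @param field optional `list(dr, dc)` displacement field (pixels).
#' @return `list(image, labels)`.
#' @export
warp_section <- function(image, labels = NULL, rotation = 0,
                         translation = c(0, 0), scale = 1, shear = 0,
                         field = NULL) {
  H <- nrow(image); W <- ncol(image)
  th <- rotation * pi / 180
  sh <- tan(shear * pi / 180)
  # sampling map: output (centered) -> input (centered)
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
    matrix(c(1, 0, sh, 1), 2, 2) / scale
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  out_r <- rep(seq_len(H), times = W) - cr
  out_c <- rep(seq_len(W), each = H) - cc
  src_r <- A[1, 1] * out_r + A[1, 2] * out_c + cr - translation[1]
  src_c <- A[2, 1] * out_r + A[2, 2] * out_c + cc - translation[2]
  if (!is.null(field)) {
    src_r <- src_r + as.vector(field$dr)
    src_c <- src_c + as.vector(field$dc)
  }
  out <- list(image = matrix(bilinear_sample(image, src_r, src_c), H, W))
  if (!is.null(labels)) {
    lab <- nearest_sample(labels, src_r, src_c)
    out$labels <- matrix(as.integer(lab), H, W)
  }
  out
}

#' Draw one random augmentation of an (image, labels) pair
#'
#' Samples rotation, translation, log-scale, shear, brightness, contrast
#' and a nonlinear displacement field from `config`, applies them, and
#' randomly crops to `min(crop, image size)`. Draws come from the current
#' RNG stream, so a fixed seed reproduces the augmented pair.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param labels optional integer label matrix (`NA` allowed).
#' @param config an [augmentation_config()].
#' @return `list(image, labels, params)` where `params` records the draw.
#' @export
sample_augmentation <- function(image, labels = NULL,
                                config = augmentation_config()) {
  H <- nrow(image); W <- ncol(image)
  par <- list(
    rotation = stats::runif(1, config$rotation[1], config$rotation[2]),
    translation = stats::runif(2, config$translation[1], config$translation[2]),
    scale = exp(stats::runif(1, log(config$scale[1]), log(config$scale[2]))),
    shear = stats::runif(1, config$shear[1], config$shear[2]),
    brightness = stats::runif(1, config$brightness[1], config$brightness[2]),
    contrast = stats::runif(1, config$contrast[1], config$contrast[2]))
  field <- random_displacement_field(H, W, config$warp_sd, config$warp_spacing)
  w <- warp_section(image, labels, rotation = par$rotation,
                    translation = par$translation, scale = par$scale,
                    shear = par$shear, field = field)
  img <- w$image
  m <- mean(img)
  img <- m + (img - m) * par$contrast + par$brightness / 255
  img <- pmin(pmax(img, 0), 1)
  ch <- min(config$crop, H); cw <- min(config$crop, W)
  r0 <- if (ch < H) sample.int(H - ch + 1L, 1L) else 1L
  c0 <- if (cw < W) sample.int(W - cw + 1L, 1L) else 1L
  img <- img[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  out <- list(image = img, params = par)
  if (!is.null(labels))
    out$labels <- w$labels[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  out
}
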