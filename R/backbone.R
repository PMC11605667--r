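# pluggable segmentation backbone.
#
# the framework only requires a model honouring a small contract:
#   predict_probs()      full-resolution, softmax-normalised C-channel maps
#   stochastic_predict() the same with dropout active (rate 0 == predict)
#   train_backbone()     SGD with momentum / weight decay on a pixel loss
# the default backbone is a compact per-pixel multilayer perceptron over
# multiscale features (intensity, Gaussian-smoothed intensity at two
# scales, normalised coordinates) with one hidden layer and test-time
# dropout on the hidden units. any stronger model implementing the same
# contract is a drop-in replacement.

# run code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing with replicate padding
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- 0
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- if (along_rows) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
      out <- out + k[o + r + 1L] * shifted
    }
    out
  }
  conv_axis(conv_axis(m, TRUE), FALSE)
}

#' Create the default MLP backbone
#'
#' A per-pixel softmax classifier: each pixel is described by its
#' intensity, Gaussian-smoothed intensities at `sigmas`, and normalised
#' (x, y) coordinates; a single hidden ReLU layer feeds a C-way softmax.
#' Weights are He-initialised from `seed`. `dropout_rate` applies to the
#' hidden units in [stochastic_predict()] only (test-time dropout for
#' Monte Carlo sampling); deterministic prediction never drops units.
#'
#' @param n_classes number of classes C.
#' @param hidden hidden-layer width, default 16.
#' @param sigmas smoothing scales (pixels) of the context features.
#' @param dropout_rate test-time dropout probability, default 0.5.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `mlp_backbone`.
#' @export
new_mlp_backbone <- function(n_classes, hidden = 16L, sigmas = c(1.5, 3),
                             dropout_rate = 0.5, seed = 1L) {
  n_feat <- 3L + length(sigmas)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(n_feat * hidden, sd = sqrt(2 / n_feat)), n_feat, hidden)
    W2 <- matrix(stats::rnorm(hidden * n_classes, sd = sqrt(2 / hidden)), hidden, n_classes)
  })
  structure(list(W1 = W1, b1 = numeric(hidden), W2 = W2,
                 b2 = numeric(n_classes), n_classes = as.integer(n_classes),
                 sigmas = sigmas, dropout_rate = dropout_rate,
                 velocity = NULL),
            class = "mlp_backbone")
}

#' @export
print.mlp_backbone <- function(x, ...) {
  cat(sprintf("<mlp_backbone> %d features -> %d hidden -> %d classes, dropout %.2f\n",
              nrow(x$W1), ncol(x$W1), x$n_classes, x$dropout_rate))
  invisible(x)
}

# pixel feature matrix (H*W x F, column-major pixel order)
backbone_features <- function(backbone, image) {
  H <- nrow(image); W <- ncol(image)
  cols <- c(list(as.vector(image)),
            lapply(backbone$sigmas, function(s) as.vector(gaussian_blur(image, s))),
            list(rep((seq_len(W) - 0.5) / W, each = H),
                 rep((seq_len(H) - 0.5) / H, times = W)))
  do.call(cbind, cols)
}

softmax_rows <- function(z) {
  m <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

forward_mlp <- function(backbone, X, drop_mask = NULL) {
  n <- nrow(X)
  Z1 <- X %*% backbone$W1
  Z1 <- Z1 + rep(backbone$b1, each = n)
  A1 <- (Z1 > 0) * Z1
  if (!is.null(drop_mask)) A1 <- A1 * rep(drop_mask, each = n)
  Z2 <- A1 %*% backbone$W2
  Z2 <- Z2 + rep(backbone$b2, each = n)
  list(Z1 = Z1, A1 = A1, P = softmax_rows(Z2))
}

#' Deterministic class-probability maps for one section
#'
#' @param backbone an `mlp_backbone`.
#' @param image numeric H x W matrix in \[0, 1\].
#' @param features optional pre-computed feature matrix (speed-up).
#' @return H x W x C array of softmax probabilities (channels sum to 1).
#' @export
predict_probs <- function(backbone, image, features = NULL) {
  if (is.null(features)) features <- backbone_features(backbone, image)
  P <- forward_mlp(backbone, features)$P
  array(P, dim = c(nrow(image), ncol(image), backbone$n_classes))
}

#' Stochastic prediction with test-time dropout
#'
#' One Monte Carlo forward pass: hidden units are dropped independently
#' with probability `dropout_rate` (inverted-dropout scaling keeps the
#' expectation unchanged). With `dropout_rate = 0` this equals
#' [predict_probs()] exactly.
#'
#' @inheritParams predict_probs
#' @param sample_seed integer seed for the dropout draw (reproducible).
#' @return H x W x C probability array.
#' @export
stochastic_predict <- function(backbone, image, sample_seed, features = NULL) {
  p <- backbone$dropout_rate
  if (p <= 0) return(predict_probs(backbone, image, features))
  if (is.null(features)) features <- backbone_features(backbone, image)
  keep <- with_seed(sample_seed,
                    stats::rbinom(ncol(backbone$W1), 1L, 1 - p)) / (1 - p)
  P <- forward_mlp(backbone, features, drop_mask = keep)$P
  array(P, dim = c(nrow(image), ncol(image), backbone$n_classes))
}

#' Training configuration
#'
#' @param initial_epochs epochs of the bootstrap training, default 200.
#' @param finetune_epochs epochs per active-learning iteration, default 10.
#' @param batch_size sections per SGD step, default 8.
#' @param momentum SGD momentum, default 0.9.
#' @param lr_initial,lr_finetune learning rates; the fine-tuning rate is a
#'   tenth of the initial one by default.
#' @param weight_decay L2 penalty weight, default 1e-4.
#' @param crop training crop side (pixels), default 128; sections smaller
#'   than the crop are used whole.
#' @param augment apply random geometric/intensity augmentation, default
#'   `FALSE` at desk scale.
#' @param seed base seed for shuffling/augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_epochs = 200L, finetune_epochs = 10L,
                         batch_size = 8L, momentum = 0.9,
                         lr_initial = 0.2, lr_finetune = lr_initial / 10,
                         weight_decay = 1e-4, crop = 128L, augment = FALSE,
                         seed = 1L) {
  cfg <- list(initial_epochs = as.integer(initial_epochs),
              finetune_epochs = as.integer(finetune_epochs),
              batch_size = as.integer(batch_size), momentum = momentum,
              lr_initial = lr_initial, lr_finetune = lr_finetune,
              weight_decay = weight_decay, crop = as.integer(crop),
              augment = isTRUE(augment), seed = as.integer(seed))
  stopifnot(cfg$initial_epochs >= 0, cfg$finetune_epochs >= 0,
            cfg$batch_size > 0, cfg$lr_initial > 0, cfg$weight_decay >= 0)
  structure(cfg, class = "train_config")
}

# gradient of the per-pixel-averaged training loss w.r.t. the logits,
# for a batch of concatenated sections (each section has its own
# compatible set). labelled pixel: softmax - onehot. unlabelled pixel
# (mixed loss): the merged-background term f_c - f_c * [c in Cn] / s with
# s = sum_{Cn} f; outside Cn the derivative of -log s is +f_c. also
# returns the summed loss value of the contributing pixels.
batch_logit_gradient <- function(P, lab_vec, sec_of_row, cn_cols, loss) {
  G <- matrix(0, nrow(P), ncol(P))
  total_loss <- 0
  li <- which(!is.na(lab_vec))
  n_contrib <- 0L
  if (length(li) > 0L) {
    G[li, ] <- P[li, , drop = FALSE]
    idx <- cbind(li, lab_vec[li] + 1L)
    G[idx] <- G[idx] - 1
    total_loss <- total_loss - sum(log(pmax(P[idx], 1e-12)))
    n_contrib <- n_contrib + length(li)
  }
  if (loss == "mixed") {
    for (n in unique(sec_of_row)) {
      ui <- which(is.na(lab_vec) & sec_of_row == n)
      if (length(ui) == 0L) next
      cn <- cn_cols[[n]]
      if (length(cn) == 0L)
        stop("unlabelled pixels with an empty compatible set")
      s <- pmax(rowSums(P[ui, cn, drop = FALSE]), 1e-12)
      Gu <- P[ui, , drop = FALSE]
      Gu[, cn] <- Gu[, cn] * (1 - 1 / s)
      G[ui, ] <- Gu
      total_loss <- total_loss - sum(log(s))
      n_contrib <- n_contrib + length(ui)
    }
  }
  list(G = G, n = n_contrib, loss = total_loss)
}

#' Train or fine-tune a backbone on the current annotation state
#'
#' Minimises the mixed cross-entropy (or, for the cross-entropy ablation,
#' the standard cross-entropy over labelled pixels only) plus an L2 weight
#' penalty, with minibatch SGD + momentum over sections. Deterministic
#' given `config$seed`. Aborts with diagnostics if the loss diverges.
#'
#' @param backbone an `mlp_backbone`.
#' @param stack an [image_stack()].
#' @param state an [annotation_state()].
#' @param config a [train_config()].
#' @param phase `"initial"` or `"finetune"` (selects epochs and rate).
#' @param loss `"mixed"` (default) or `"ce"`.
#' @return The fitted backbone; the per-epoch loss log is attached as
#'   `attr(,"history")` (tibble: epoch, loss, lr).
#' @export
train_backbone <- function(backbone, stack, state, config = train_config(),
                           phase = c("initial", "finetune"),
                           loss = c("mixed", "ce")) {
  phase <- match.arg(phase)
  loss <- match.arg(loss)
  epochs <- if (phase == "initial") config$initial_epochs else config$finetune_epochs
  lr <- if (phase == "initial") config$lr_initial else config$lr_finetune
  hist <- tibble::tibble(epoch = integer(), loss = numeric(), lr = numeric())
  if (epochs == 0L) {
    attr(backbone, "history") <- hist
    return(backbone)
  }
  N <- stack$n_sections
  feats <- lapply(stack$sections, function(s) backbone_features(backbone, s))
  cn_cols <- lapply(seq_len(N), function(n) compatible_classes(state, n) + 1L)
  shapes <- list(W1 = dim(backbone$W1), b1 = length(backbone$b1),
                 W2 = dim(backbone$W2), b2 = length(backbone$b2))
  vel <- backbone$velocity
  if (is.null(vel)) {
    vel <- list(W1 = backbone$W1 * 0, b1 = backbone$b1 * 0,
                W2 = backbone$W2 * 0, b2 = backbone$b2 * 0)
  }
  losses <- numeric(epochs)
  with_seed(config$seed + if (phase == "initial") 0L else 1L, {
    for (ep in seq_len(epochs)) {
      order <- sample.int(N)
      ep_loss <- 0; ep_pix <- 0L
      for (b0 in seq(1L, N, by = config$batch_size)) {
        batch <- order[b0:min(b0 + config$batch_size - 1L, N)]
        secs <- lapply(batch, function(n)
          training_section(backbone, stack, state, n, feats, config))
        X <- do.call(rbind, lapply(secs, `[[`, "X"))
        lab <- unlist(lapply(secs, `[[`, "lab"))
        sec_of_row <- rep(batch, vapply(secs, function(s) length(s$lab), integer(1)))
        fw <- forward_mlp(backbone, X)
        lg <- batch_logit_gradient(fw$P, lab, sec_of_row, cn_cols, loss)
        if (lg$n == 0L) next
        G <- lg$G
        gW2 <- crossprod(fw$A1, G) / lg$n + config$weight_decay * backbone$W2
        gb2 <- colSums(G) / lg$n
        dZ1 <- (G %*% t(backbone$W2)) * (fw$Z1 > 0)
        gW1 <- crossprod(X, dZ1) / lg$n + config$weight_decay * backbone$W1
        gb1 <- colSums(dZ1) / lg$n
        vel$W1 <- config$momentum * vel$W1 - lr * gW1
        vel$b1 <- config$momentum * vel$b1 - lr * gb1
        vel$W2 <- config$momentum * vel$W2 - lr * gW2
        vel$b2 <- config$momentum * vel$b2 - lr * gb2
        backbone$W1 <- backbone$W1 + vel$W1
        backbone$b1 <- backbone$b1 + vel$b1
        backbone$W2 <- backbone$W2 + vel$W2
        backbone$b2 <- backbone$b2 + vel$b2
        ep_loss <- ep_loss + lg$loss
        ep_pix <- ep_pix + lg$n
      }
      mean_loss <- if (ep_pix > 0L) ep_loss / ep_pix else NA_real_
      if (!is.na(mean_loss) && !is.finite(mean_loss))
        stop(sprintf("training diverged at epoch %d (loss = %s); try a lower learning rate",
                     ep, format(mean_loss)))
      losses[ep] <- mean_loss
    }
  })
  hist <- tibble::tibble(epoch = seq_len(epochs), loss = losses, lr = lr)
  backbone$velocity <- vel
  attr(backbone, "history") <- hist
  backbone
}

# one training view of a section: feature rows + partial label vector,
# optionally augmented and cropped
training_section <- function(backbone, stack, state, n, feats, config) {
  img <- stack$sections[[n]]
  lab <- state$labels[[n]]
  H <- nrow(img); W <- ncol(img)
  if (config$augment) {
    aug <- sample_augmentation(img, lab)
    X <- backbone_features(backbone, aug$image)
    lab <- aug$labels
    H <- nrow(aug$image); W <- ncol(aug$image)
  } else {
    X <- feats[[n]]
  }
  ch <- min(config$crop, H); cw <- min(config$crop, W)
  if (ch < H || cw < W) {
    r0 <- sample.int(H - ch + 1L, 1L) - 1L
    c0 <- sample.int(W - cw + 1L, 1L) - 1L
    rows <- as.vector(outer((r0 + 1L):(r0 + ch), ((c0):(c0 + cw - 1L)) * H, "+"))
    X <- X[rows, , drop = FALSE]
    lab <- lab[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), drop = FALSE]
  }
  list(X = X, lab = as.vector(lab))
}

#' Initial semi-supervised training
#'
#' Fits the backbone from scratch on the bootstrap annotations and weak
#' bounds with the mixed loss (every class must be annotated at least once).
#'
#' @inheritParams train_backbone
#' @return The fitted backbone (per-epoch loss log in `attr(,"history")`).
#' @export
initial_train <- function(backbone, stack, state, config = train_config(),
                          loss = c("mixed", "ce")) {
  if (any(colSums(state$A) == 0L))
    stop("initial training requires >= 1 annotation of every class")
  train_backbone(backbone, stack, state, config, phase = "initial",
                 loss = match.arg(loss))
}

#' Fine-tune after a new annotation
#'
#' @inheritParams train_backbone
#' @return The updated backbone.
#' @export
finetune <- function(backbone, stack, state, config = train_config(),
                     loss = c("mixed", "ce")) {
  train_backbone(backbone, stack, state, config, phase = "finetune",
                 loss = match.arg(loss))
}

#' Save / load a backbone checkpoint
#' @param backbone an `mlp_backbone`. @param path file path.
#' @return `path` / the restored backbone.
#' @export
save_backbone <- function(backbone, path) {
  saveRDS(backbone, path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) readRDS(path)
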