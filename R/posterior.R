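# mixed cross-entropy, constrained posterior, hard segmentation, entropy
# and Monte Carlo dropout estimates.

#' Mixed cross-entropy of one section
#'
#' Cross-entropy extended to partially annotated sections: labelled pixels
#' contribute the usual `-log f_l(x)`; unlabelled pixels contribute
#' `-log sum_{c in Cn} f_c(x)`, the probability merged over the compatible
#' set. On a fully labelled section this is exactly the classical
#' cross-entropy. Log arguments are floored at `1e-12`.
#'
#' @param probs H x W x C probability array (each pixel sums to 1).
#' @param labels H x W integer matrix of 0-based class ids, `NA` where
#'   unlabelled.
#' @param cn integer vector of compatible class ids for the unlabelled
#'   pixels of this section.
#' @param average divide by the number of pixels? Default `FALSE` (sum).
#' @return non-negative numeric.
#' @export
mixed_cross_entropy <- function(probs, labels, cn, average = FALSE) {
  C <- dim(probs)[3]
  P <- matrix(probs, ncol = C)
  lab <- as.vector(labels)
  li <- which(!is.na(lab))
  ui <- which(is.na(lab))
  if (length(ui) > 0L && length(cn) == 0L)
    stop("unlabelled pixels with an empty compatible set")
  v <- 0
  if (length(li) > 0L)
    v <- v - sum(log(pmax(P[cbind(li, lab[li] + 1L)], 1e-12)))
  if (length(ui) > 0L)
    v <- v - sum(log(pmax(rowSums(P[ui, cn + 1L, drop = FALSE]), 1e-12)))
  if (average) v / length(lab) else v
}

#' Gradient of [mixed_cross_entropy()] with respect to the probabilities
#'
#' @inheritParams mixed_cross_entropy
#' @return H x W x C array of partial derivatives (zero where the floored
#'   log is flat).
#' @export
mixed_cross_entropy_grad <- function(probs, labels, cn) {
  C <- dim(probs)[3]
  P <- matrix(probs, ncol = C)
  G <- matrix(0, nrow(P), C)
  lab <- as.vector(labels)
  li <- which(!is.na(lab))
  if (length(li) > 0L) {
    p <- P[cbind(li, lab[li] + 1L)]
    G[cbind(li, lab[li] + 1L)] <- ifelse(p > 1e-12, -1 / p, 0)
  }
  ui <- which(is.na(lab))
  if (length(ui) > 0L) {
    if (length(cn) == 0L) stop("unlabelled pixels with an empty compatible set")
    s <- rowSums(P[ui, cn + 1L, drop = FALSE])
    G[ui, cn + 1L] <- ifelse(s > 1e-12, -1 / s, 0)
  }
  array(G, dim = dim(probs))
}

#' Constrained posterior of one section
#'
#' Combines the raw backbone probabilities with the annotation constraints:
#' a labelled pixel becomes one-hot at its label; an unlabelled pixel keeps
#' only the classes in its compatible set, renormalised. If the retained
#' mass is below `1e-12` the pixel falls back to uniform over the set.
#' With `constraints = "bounds_only"` the annotations are ignored: every
#' pixel is renormalised over the classes allowed by the weak bounds alone
#' (used to score the classifier against annotations without the
#' annotations trivially reproducing themselves).
#'
#' @param probs H x W x C raw probability array for section `n`.
#' @param state an [annotation_state()].
#' @param n section index.
#' @param constraints `"full"` (default) or `"bounds_only"`.
#' @return H x W x C constrained probability array.
#' @export
constrained_posterior <- function(probs, state, n,
                                  constraints = c("full", "bounds_only")) {
  constraints <- match.arg(constraints)
  C <- dim(probs)[3]
  P <- matrix(probs, ncol = C)
  if (constraints == "bounds_only") {
    cn <- bounds_compatible_classes(state, n)
    out <- matrix(0, nrow(P), C)
    out[, cn + 1L] <- renormalise_over(P[, cn + 1L, drop = FALSE])
    return(array(out, dim = dim(probs)))
  }
  cn <- compatible_classes(state, n)
  lab <- as.vector(state$labels[[n]])
  ui <- which(is.na(lab))
  if (length(ui) > 0L && length(cn) == 0L)
    stop("unlabelled pixels with an empty compatible set")
  out <- matrix(0, nrow(P), C)
  li <- which(!is.na(lab))
  if (length(li) > 0L) out[cbind(li, lab[li] + 1L)] <- 1
  if (length(ui) > 0L)
    out[ui, cn + 1L] <- renormalise_over(P[ui, cn + 1L, drop = FALSE])
  array(out, dim = dim(probs))
}

renormalise_over <- function(M) {
  s <- rowSums(M)
  low <- s < 1e-12
  if (any(low)) {
    M[low, ] <- 1
    s[low] <- ncol(M)
  }
  M / s
}

#' Hard segmentation from a posterior
#'
#' Per-pixel argmax; ties go to the lowest class id.
#'
#' @param post H x W x C probability array.
#' @return H x W integer matrix of 0-based class ids.
#' @export
hard_segmentation <- function(post) {
  C <- dim(post)[3]
  P <- matrix(post, ncol = C)
  lab <- max.col(P, ties.method = "first") - 1L
  matrix(as.integer(lab), dim(post)[1], dim(post)[2])
}

#' Mean per-pixel entropy contribution of one class
#'
#' `H_nc = -(1/|Omega|) sum_x p_c(x) log p_c(x)` with natural log and
#' `0 log 0 := 0`.
#'
#' @param post H x W x C probability array.
#' @param c class id (0-based).
#' @return non-negative numeric.
#' @export
class_entropy <- function(post, c) {
  p <- post[, , c + 1L]
  t <- ifelse(p > 0, p * log(p), 0)
  -sum(t) / length(p)
}

#' Monte Carlo dropout posterior of one section
#'
#' Averages `S` stochastic forward passes (dropout active), each combined
#' with the annotation constraints via [constrained_posterior()]. With
#' `dropout_rate = 0` the result equals the deterministic constrained
#' posterior.
#'
#' @param backbone an `mlp_backbone`.
#' @param image the section's intensity matrix.
#' @param state an [annotation_state()].
#' @param n section index.
#' @param S number of Monte Carlo samples, default 20.
#' @param seed base seed; sample s uses `seed + s`.
#' @param features optional pre-computed feature matrix.
#' @return H x W x C probability array.
#' @export
mc_dropout_posterior <- function(backbone, image, state, n, S = 20L,
                                 seed = 1L, features = NULL) {
  if (S < 1L) stop("S must be >= 1")
  if (is.null(features)) features <- backbone_features(backbone, image)
  acc <- 0
  for (s in seq_len(S)) {
    raw <- stochastic_predict(backbone, image, sample_seed = seed + s,
                              features = features)
    acc <- acc + constrained_posterior(raw, state, n)
  }
  acc / S
}
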