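# per-class Dice tracking, the smoothed Dice predictor, and the query
# selection criteria (proposed criterion, ablations, baselines).

#' Dice coefficient of two binary masks
#'
#' `2|P n R| / (|P| + |R|)`; two empty masks score 1, exactly one empty
#' mask scores 0.
#'
#' @param pred,ref logical matrices (or vectors) of equal length.
#' @return numeric in \[0, 1\].
#' @export
dice_coefficient <- function(pred, ref) {
  p <- as.logical(pred); r <- as.logical(ref)
  sp <- sum(p); sr <- sum(r)
  if (sp + sr == 0L) return(1)
  2 * sum(p & r) / (sp + sr)
}

#' Per-class Dice of the current classifier
#'
#' Two evaluation scopes. `"query"` scores the classifier against the
#' *manual annotations*: on every section where class `c` is annotated,
#' the predicted mask is the argmax of the raw posterior renormalised over
#' the bounds-compatible classes (annotation constraints removed, so the
#' annotations cannot trivially reproduce themselves), and the per-section
#' Dice values are averaged. `"eval"` scores the full constrained
#' posterior's hard segmentation against complete ground truth, pooling
#' intersection and mask sizes over the whole stack.
#'
#' @param raw_probs list of H x W x C raw probability arrays, one per
#'   section (as returned by [predict_probs()]).
#' @param state an [annotation_state()].
#' @param c class id (0-based).
#' @param scope `"query"` or `"eval"`.
#' @param gt ground-truth [label_stack()] (required for `scope = "eval"`).
#' @return numeric in \[0, 1\].
#' @export
per_class_dice <- function(raw_probs, state, c, scope = c("query", "eval"),
                           gt = NULL) {
  scope <- match.arg(scope)
  if (!c %in% state$catalog$class_ids) stop("invalid class id")
  if (scope == "query") {
    secs <- which(state$A[, as.character(c)] == 1L)
    if (length(secs) == 0L) return(0)
    d <- vapply(secs, function(n) {
      post <- constrained_posterior(raw_probs[[n]], state, n,
                                    constraints = "bounds_only")
      dice_coefficient(hard_segmentation(post) == c, annotated_mask(state, n, c))
    }, numeric(1))
    mean(d)
  } else {
    if (is.null(gt)) stop("eval scope needs ground truth")
    inter <- 0; sz <- 0
    for (n in seq_len(state$n_sections)) {
      post <- constrained_posterior(raw_probs[[n]], state, n)
      pred <- hard_segmentation(post) == c
      ref <- class_mask(gt, n, c)
      inter <- inter + sum(pred & ref)
      sz <- sz + sum(pred) + sum(ref)
    }
    if (sz == 0) 1 else 2 * inter / sz
  }
}

#' Smoothed Dice prediction
#'
#' `D~_c(T) = alpha * D_c(T-1) + (1 - alpha) * D_c(T-2)`, balancing the
#' latest and the previous observed Dice of class `c`. At the first
#' iteration the missing `D_c(T-2)` is taken equal to `D_c(T-1)`.
#'
#' @param history numeric matrix of recorded Dice values, one row per
#'   iteration, columns named by class id (a `dice_history`).
#' @param c class id (0-based).
#' @param alpha smoothing weight in \[0, 1\], default 0.5.
#' @return numeric in \[0, 1\].
#' @export
predict_dice <- function(history, c, alpha = 0.5) {
  col <- history[, as.character(c)]
  T1 <- length(col)
  if (T1 == 0L) stop("empty Dice history")
  last <- col[[T1]]
  prev <- if (T1 >= 2L) col[[T1 - 1L]] else last
  alpha * last + (1 - alpha) * prev
}

#' Queryable (section, class) pairs
#'
#' All pairs with the class still compatible with the section (inside its
#' weak bounds and not yet annotated there). An empty pool means the stack
#' is exhausted.
#'
#' @param state an [annotation_state()].
#' @return tibble with columns `n`, `c`, ordered by section then class.
#' @export
candidate_pairs <- function(state) {
  rows <- lapply(seq_len(state$n_sections), function(n) {
    cs <- compatible_classes(state, n)
    if (length(cs) == 0L) return(NULL)
    tibble::tibble(n = n, c = cs)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(n = integer(), c = integer()) else out
}

strategy_names <- c("BDalpha", "Dalpha", "BDalpha_CE", "HBDalpha", "HDalpha",
                    "HB", "H", "H_dropout", "rand", "uniform")

#' Score the candidate pool under a query strategy
#'
#' Implements the proposed criterion and its ablations. With `R` the
#' remaining-effort estimate, `H` the per-pair entropy and `D~` the
#' smoothed Dice prediction:
#' \itemize{
#'   \item `BDalpha` (proposed) and `BDalpha_CE`: `(1 - D~_c) / R_nc`
#'   \item `Dalpha`: same ratio with shared boundary lengths ablated
#'     (the caller zeroes the off-diagonal of `B` before computing `R`)
#'   \item `HBDalpha`: `(1 - D~_c) * H_nc / R_nc`
#'   \item `HDalpha`: `(1 - D~_c) * H_nc`
#'   \item `HB`: `H_nc / R_nc`
#'   \item `H`, `H_dropout`: `H_nc` (deterministic / MC-averaged posterior)
#' }
#' A zero (or negative) remaining effort in a ratio strategy scores `+Inf`:
#' annotations predicted to be free are queried first.
#'
#' @param strategy strategy name (see above; `rand`/`uniform` do not score).
#' @param pool tibble of candidates from [candidate_pairs()].
#' @param dtilde numeric vector of smoothed Dice predictions named by
#'   class id.
#' @param R N x C remaining-effort matrix (columns named by class id).
#' @param entropy N x C per-pair entropy matrix (H-variants only).
#' @return `pool` with `score` and `dtilde` columns appended.
#' @export
score_candidates <- function(strategy, pool, dtilde = NULL, R = NULL,
                             entropy = NULL) {
  if (!strategy %in% strategy_names) stop("unknown strategy: ", strategy)
  if (strategy %in% c("rand", "uniform"))
    stop(strategy, " is not score-based")
  idx <- cbind(pool$n, match(as.character(pool$c), colnames(R %||% entropy)))
  dt <- if (is.null(dtilde)) rep(0, nrow(pool)) else dtilde[as.character(pool$c)]
  room <- 1 - dt
  h <- if (!is.null(entropy)) entropy[idx] else NULL
  r <- if (!is.null(R)) R[idx] else NULL
  score <- switch(strategy,
    BDalpha = ,
    BDalpha_CE = ,
    Dalpha = ratio_score(room, r),
    HBDalpha = ratio_score(room * h, r),
    HDalpha = room * h,
    HB = ratio_score(h, r),
    H = ,
    H_dropout = h)
  dplyr::mutate(pool, score = unname(score), dtilde = unname(dt))
}

ratio_score <- function(num, r) {
  if (is.null(r)) stop("this strategy needs the remaining-effort table")
  ifelse(r <= 0, Inf, num / r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the highest-scoring query
#'
#' Deterministic argmax over a scored pool: ties are broken by larger room
#' for improvement `1 - D~_c`, then lower class id, then lower section id.
#'
#' @param scores tibble from [score_candidates()].
#' @return `list(n, c)`.
#' @export
select_query <- function(scores) {
  if (nrow(scores) == 0L) stop("empty candidate pool")
  o <- order(-scores$score, scores$dtilde, scores$c, scores$n)[1]
  list(n = scores$n[o], c = scores$c[o])
}

#' Slice-wise uniform baseline
#'
#' Finishes the current section first (annotating its remaining compatible
#' classes in random order); when the section is complete, opens the
#' section that minimises the maximum run of consecutive sections still
#' without any annotation, breaking ties uniformly at random. Draws come
#' from the current RNG stream.
#'
#' @param state an [annotation_state()].
#' @param current_section the section being worked on, or `NULL`.
#' @return `list(n, c)`.
#' @export
select_uniform <- function(state, current_section = NULL) {
  if (!is.null(current_section)) {
    cs <- compatible_classes(state, current_section)
    if (length(cs) > 0L)
      return(list(n = current_section, c = sample_one(cs)))
  }
  cand <- which(vapply(seq_len(state$n_sections),
                       function(n) length(compatible_classes(state, n)) > 0L,
                       logical(1)))
  if (length(cand) == 0L) stop("empty candidate pool")
  covered <- rowSums(state$A) > 0L
  gaps <- vapply(cand, function(n) {
    cv <- covered; cv[n] <- TRUE
    max_uncovered_run(cv)
  }, integer(1))
  best <- cand[gaps == min(gaps)]
  n <- sample_one(best)
  list(n = n, c = sample_one(compatible_classes(state, n)))
}

max_uncovered_run <- function(covered) {
  best <- 0L; run <- 0L
  for (v in covered) {
    run <- if (v) 0L else run + 1L
    best <- max(best, run)
  }
  best
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Random-selection baseline
#'
#' Uniform over the candidate pool; draws from the current RNG stream.
#'
#' @param state an [annotation_state()].
#' @return `list(n, c)`.
#' @export
select_random <- function(state) {
  pool <- candidate_pairs(state)
  if (nrow(pool) == 0L) stop("empty candidate pool")
  i <- sample.int(nrow(pool), 1L)
  list(n = pool$n[i], c = pool$c[i])
}
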