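# boundary-length geometry and the annotation-effort model.
#
# boundary length is measured in "crack" units: cut edges of the
# 4-adjacency pixel grid. an edge is counted when its two incident pixels
# straddle the mask boundary, and the grid edges of mask pixels lying on
# the image border are counted too. with this convention the boundary of a
# fully labelled section decomposes exactly into pairwise shared boundaries
# plus border edges, which the remaining-effort subtraction relies on.

#' Boundary length of a binary mask, in crack edges
#'
#' Counts 4-adjacency pixel pairs with exactly one pixel inside the mask,
#' plus the grid edges of mask pixels on the image border.
#'
#' @param mask logical matrix.
#' @return non-negative integer.
#' @export
crack_length <- function(mask) {
  m <- as.matrix(mask) != 0
  if (!any(m)) return(0L)
  H <- nrow(m); W <- ncol(m)
  internal <- 0L
  if (W > 1L) internal <- internal + sum(xor(m[, -W, drop = FALSE], m[, -1, drop = FALSE]))
  if (H > 1L) internal <- internal + sum(xor(m[-H, , drop = FALSE], m[-1, , drop = FALSE]))
  border <- sum(m[1, ]) + sum(m[H, ]) + sum(m[, 1]) + sum(m[, W])
  as.integer(internal + border)
}

#' Boundary length shared by two disjoint masks
#'
#' Counts unordered 4-adjacent pixel pairs with one pixel in each mask.
#' Symmetric in its arguments; tracing this stretch once delineates both
#' structures.
#'
#' @param mask_a,mask_b disjoint logical matrices of equal dimension.
#' @return non-negative integer.
#' @export
shared_crack_length <- function(mask_a, mask_b) {
  a <- as.matrix(mask_a) != 0
  b <- as.matrix(mask_b) != 0
  if (!identical(dim(a), dim(b))) stop("masks must share dimensions")
  if (any(a & b)) stop("masks overlap")
  H <- nrow(a); W <- ncol(a)
  n <- 0L
  if (W > 1L) {
    n <- n + sum(a[, -W, drop = FALSE] & b[, -1, drop = FALSE]) +
      sum(b[, -W, drop = FALSE] & a[, -1, drop = FALSE])
  }
  if (H > 1L) {
    n <- n + sum(a[-H, , drop = FALSE] & b[-1, , drop = FALSE]) +
      sum(b[-H, , drop = FALSE] & a[-1, , drop = FALSE])
  }
  as.integer(n)
}

#' Cumulative boundary statistics
#'
#' Recomputes from scratch the symmetric C x C matrix `B` of running
#' average boundary lengths: `B[c,c]` is the mean crack length of class c
#' over its annotated instances, `B[c,c']` the mean shared length over
#' sections where c and c' are co-annotated. Averages use a weak prior
#' constant `epsilon` in the denominator, which in particular keeps a
#' pair's shared length at exactly 0 until the pair has been co-annotated.
#'
#' @param state an [annotation_state()].
#' @param epsilon weak-prior constant, default `0.01`.
#' @return A `boundary_stats` object: `B` (C x C), `count` (per-class
#'   annotated instances), `pair_count` (co-annotation counts), `epsilon`.
#' @export
update_boundary_stats <- function(state, epsilon = 0.01) {
  ids <- state$catalog$class_ids
  C <- length(ids)
  B <- matrix(0, C, C, dimnames = list(ids, ids))
  count <- stats::setNames(colSums(state$A), ids)
  pair_count <- matrix(0L, C, C, dimnames = list(ids, ids))
  masks <- vector("list", C)
  for (n in seq_len(state$n_sections)) {
    ann <- which(state$A[n, ] == 1L)
    for (j in ann) masks[[j]] <- annotated_mask(state, n, ids[j])
    for (j in ann) B[j, j] <- B[j, j] + crack_length(masks[[j]])
    if (length(ann) > 1L) {
      for (j in ann) {
        for (k in ann) {
          if (j < k) {
            s <- shared_crack_length(masks[[j]], masks[[k]])
            B[j, k] <- B[j, k] + s
            B[k, j] <- B[k, j] + s
            pair_count[j, k] <- pair_count[j, k] + 1L
            pair_count[k, j] <- pair_count[k, j] + 1L
          }
        }
      }
    }
  }
  diag_den <- epsilon + count
  off_den <- epsilon + pair_count
  out <- B / off_den
  diag(out) <- diag(B) / diag_den
  structure(list(B = out, count = count, pair_count = pair_count,
                 epsilon = epsilon),
            class = "boundary_stats")
}

#' Estimated remaining tracing effort for one (section, class) pair
#'
#' The expected boundary length still to trace for class c in section n:
#' its average boundary length minus the average lengths it shares with
#' classes already annotated in that section, clamped at zero. Pairs not
#' compatible with the section cost nothing (they cannot be queried).
#'
#' @param stats a `boundary_stats` from [update_boundary_stats()].
#' @param state an [annotation_state()].
#' @param n section index. @param c class id (0-based).
#' @return non-negative numeric.
#' @export
remaining_effort <- function(stats, state, n, c) {
  if (!c %in% compatible_classes(state, n)) return(0)
  j <- match(as.character(c), colnames(stats$B))
  ann <- state$A[n, ] == 1L
  max(0, stats$B[j, j] - sum(stats$B[j, ann]))
}

#' Remaining-effort table for every (section, class) pair
#' @inheritParams remaining_effort
#' @return N x C numeric matrix (columns named by class id); zero wherever
#'   the class is not compatible with the section.
#' @export
effort_table <- function(stats, state) {
  ids <- state$catalog$class_ids
  R <- matrix(0, state$n_sections, length(ids),
              dimnames = list(NULL, as.character(ids)))
  for (n in seq_len(state$n_sections)) {
    for (c in compatible_classes(state, n)) {
      R[n, as.character(c)] <- remaining_effort(stats, state, n, c)
    }
  }
  R
}

#' Actual cost charged for answering one query
#'
#' The crack length of the ground-truth mask of class c in section n minus
#' every stretch already traced as part of a class annotated earlier in the
#' same section (shared boundaries are paid for once). An absent structure
#' costs 0.
#'
#' @param gt ground-truth [label_stack()].
#' @param state the [annotation_state()] *before* this annotation.
#' @param n section index. @param c class id.
#' @return non-negative integer.
#' @export
actual_annotation_cost <- function(gt, state, n, c) {
  mask <- class_mask(gt, n, c)
  if (!any(mask)) return(0L)
  cost <- crack_length(mask)
  done <- state$catalog$class_ids[state$A[n, ] == 1L]
  for (cp in setdiff(done, c)) {
    cost <- cost - shared_crack_length(mask, class_mask(gt, n, cp))
  }
  max(0L, as.integer(cost))
}

#' Total tracing cost of a fully labelled stack
#'
#' The cost of annotating every (section, class) pair, i.e. the number of
#' distinct cut edges: each inter-class edge once, each image-border edge
#' once. Independent of the order in which classes are annotated.
#'
#' @param gt complete ground-truth [label_stack()].
#' @param catalog a [class_catalog()] (defaults to the stack's own).
#' @return positive integer.
#' @export
total_annotation_cost <- function(gt, catalog = gt$catalog) {
  total <- 0L
  for (l in gt$sections) {
    H <- nrow(l); W <- ncol(l)
    inter <- 0L
    if (W > 1L) inter <- inter + sum(l[, -W, drop = FALSE] != l[, -1, drop = FALSE])
    if (H > 1L) inter <- inter + sum(l[-H, , drop = FALSE] != l[-1, , drop = FALSE])
    total <- total + inter + 2L * (H + W)
  }
  as.integer(total)
}

#' Save / load boundary statistics as JSON
#' @param stats a `boundary_stats`. @param path file path.
#' @return `path` / the restored `boundary_stats`.
#' @export
save_boundary_stats <- function(stats, path) {
  jsonlite::write_json(list(B = stats$B, count = unname(stats$count),
                            pair_count = stats$pair_count,
                            epsilon = stats$epsilon,
                            class_ids = colnames(stats$B)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_boundary_stats
#' @export
load_boundary_stats <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.character(m$class_ids)
  structure(list(B = matrix(m$B, length(ids), dimnames = list(ids, ids)),
                 count = stats::setNames(m$count, ids),
                 pair_count = matrix(as.integer(m$pair_count), length(ids),
                                     dimnames = list(ids, ids)),
                 epsilon = m$epsilon),
            class = "boundary_stats")
}

#' Write a remaining-effort table as CSV
#'
#' One row per section, one column per class id.
#'
#' @param R matrix from [effort_table()]. @param path file path.
#' @return `path`, invisibly.
#' @export
save_effort_table <- function(R, path) {
  df <- cbind(data.frame(section = seq_len(nrow(R))), as.data.frame(R))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
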