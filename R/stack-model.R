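#' Image stack
#'
#' An ordered list of 2D grayscale intensity sections. Intensities are
#' min-max rescaled to \[0, 1\] per section at construction; a constant
#' section rescales to all zeros. Sections may have differing dimensions.
#'
#' @param sections list of numeric matrices (rows x cols), one per section.
#' @param rescale rescale each section to \[0, 1\]? Default `TRUE`.
#' @return An object of class `image_stack` with elements `sections`
#'   (list of matrices in \[0, 1\]) and `n_sections`.
#' @export
image_stack <- function(sections, rescale = TRUE) {
  if (!is.list(sections) || length(sections) < 1L)
    stop("an image stack needs at least one section")
  sections <- lapply(sections, function(s) {
    s <- as.matrix(s)
    if (length(s) == 0L) stop("empty section in image stack")
    storage.mode(s) <- "double"
    if (rescale) rescale01(s) else s
  })
  structure(list(sections = sections, n_sections = length(sections)),
            class = "image_stack")
}

# min-max rescale; constant sections map to 0 (0/0 := 0)
rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf("<image_stack> %d section(s), first %dx%d, range [%.3f, %.3f]\n",
              x$n_sections, d[1], d[2],
              min(x$sections[[1]]), max(x$sections[[1]])))
  invisible(x)
}

#' Class catalog
#'
#' The label set of a segmentation problem: integer class ids `0..C-1`
#' (class ids are pixel values in indexed label images), optional names,
#' and a background id (default 0).
#'
#' @param n_classes total number of classes C (>= 2), background included.
#' @param names optional character vector of length C.
#' @param background_id background class id, default `0L`.
#' @return A `class_catalog` object.
#' @export
class_catalog <- function(n_classes, names = NULL, background_id = 0L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least two classes (background + 1)")
  ids <- seq_len(n_classes) - 1L
  if (is.null(names)) {
    names <- c("background", paste0("class_", ids[-1]))
  }
  if (length(names) != n_classes) stop("names must have length n_classes")
  if (!background_id %in% ids) stop("background_id must be a valid class id")
  structure(list(class_ids = ids, names = names,
                 background_id = as.integer(background_id)),
            class = "class_catalog")
}

#' Weak section bounds
#'
#' Per-class first/last section indices (1-based, inclusive): the weak
#' supervision stating between which sections each structure appears.
#' Background bounds are forced to the full stack.
#'
#' @param first,last integer vectors of length C (one entry per class id
#'   `0..C-1`, in order).
#' @param n_sections stack length N.
#' @param catalog a [class_catalog()].
#' @param safety_margin non-negative number of sections by which bounds are
#'   widened symmetrically (clipped to the stack). Default 0.
#' @return A `weak_bounds` object with `first`, `last` (named by class id).
#' @export
weak_bounds <- function(first, last, n_sections, catalog, safety_margin = 0L) {
  C <- length(catalog$class_ids)
  if (length(first) != C || length(last) != C)
    stop("first/last must have one entry per class")
  first <- pmax(1L, as.integer(first) - as.integer(safety_margin))
  last <- pmin(as.integer(n_sections), as.integer(last) + as.integer(safety_margin))
  bg <- catalog$background_id + 1L
  first[bg] <- 1L
  last[bg] <- as.integer(n_sections)
  if (any(first > last) || any(first < 1L) || any(last > n_sections))
    stop("bounds must satisfy 1 <= first <= last <= n_sections")
  names(first) <- names(last) <- as.character(catalog$class_ids)
  structure(list(first = first, last = last,
                 n_sections = as.integer(n_sections)),
            class = "weak_bounds")
}

#' Label stack
#'
#' Per-section integer label maps aligned with an [image_stack()]. Labels
#' are validated against the catalog; a completeness flag marks sections
#' known to be fully labelled.
#'
#' @param sections list of integer matrices with values in the catalog.
#' @param catalog a [class_catalog()].
#' @param complete logical vector (recycled) marking fully-labelled sections.
#' @return A `label_stack` object.
#' @export
label_stack <- function(sections, catalog, complete = TRUE) {
  sections <- lapply(seq_along(sections), function(n) {
    s <- as.matrix(sections[[n]])
    storage.mode(s) <- "integer"
    bad <- setdiff(unique(as.vector(s)), catalog$class_ids)
    if (length(bad) > 0)
      stop(sprintf("section %d contains label(s) outside the catalog: %s",
                   n, paste(bad, collapse = ", ")))
    s
  })
  structure(list(sections = sections, catalog = catalog,
                 n_sections = length(sections),
                 complete = rep_len(complete, length(sections))),
            class = "label_stack")
}

#' Binary mask of one class in one section
#' @param gt a [label_stack()].
#' @param n section index (1-based).
#' @param c class id (0-based).
#' @return logical matrix.
#' @export
class_mask <- function(gt, n, c) gt$sections[[n]] == c

#' Annotation state
#'
#' Bookkeeping of the active-learning loop for one stack: the N x C binary
#' annotation matrix `A`, per-section partial label maps (`NA` = unlabelled,
#' otherwise the 0-based class id), the weak bounds and the catalog. The
#' labelled set Ln of a section is the set of non-`NA` pixels; Un is its
#' complement; the compatible set Cn is derived by [compatible_classes()].
#'
#' @param dims list of `c(rows, cols)` per section (or a single pair reused).
#' @param bounds a [weak_bounds()].
#' @param catalog a [class_catalog()].
#' @return An `annotation_state` with all-zero `A` and fully unlabelled maps.
#' @export
annotation_state <- function(dims, bounds, catalog) {
  N <- bounds$n_sections
  if (!is.list(dims)) dims <- rep(list(dims), N)
  if (length(dims) != N) stop("need one dimension pair per section")
  labels <- lapply(dims, function(d)
    matrix(NA_integer_, nrow = d[1], ncol = d[2]))
  C <- length(catalog$class_ids)
  A <- matrix(0L, nrow = N, ncol = C,
              dimnames = list(NULL, as.character(catalog$class_ids)))
  structure(list(A = A, labels = labels, bounds = bounds, catalog = catalog,
                 n_sections = N, implied = rep(FALSE, N)),
            class = "annotation_state")
}

#' Compatible classes of a section
#'
#' The set Cn of class ids an unlabelled pixel of section `n` may still
#' take: classes within their weak bounds that have not yet been annotated
#' in this section.
#'
#' @param state an [annotation_state()].
#' @param n section index (1-based).
#' @return integer vector of 0-based class ids (possibly empty), sorted.
#' @export
compatible_classes <- function(state, n) {
  if (n < 1L || n > state$n_sections) stop("section index out of range")
  ids <- state$catalog$class_ids
  in_bounds <- state$bounds$first <= n & n <= state$bounds$last
  sort(ids[in_bounds & state$A[n, ] == 0L])
}

# classes allowed in section n by the weak bounds alone (annotation ignored)
bounds_compatible_classes <- function(state, n) {
  ids <- state$catalog$class_ids
  sort(ids[state$bounds$first <= n & n <= state$bounds$last])
}

#' Record one annotation
#'
#' Adds the binary mask of class `c` in section `n` to the state: flips
#' `A[n, c]`, labels the mask pixels, and shrinks Cn by `{c}`. An empty mask
#' is a legal answer (the structure is absent in `n`, e.g. inside a safety
#' margin) and still marks the pair annotated. If a single compatible class
#' remains afterwards, the section is flagged as implied (its remaining
#' unlabelled pixels can only carry that label); the pixels are not moved
#' to Ln.
#'
#' @param state an [annotation_state()].
#' @param n section index. @param c class id (0-based).
#' @param mask logical matrix matching the section dimensions.
#' @return The updated `annotation_state`.
#' @export
apply_annotation <- function(state, n, c, mask) {
  cn <- compatible_classes(state, n)
  if (state$A[n, as.character(c)] == 1L)
    stop(sprintf("(section %d, class %d) is already annotated", n, c))
  if (!c %in% cn)
    stop(sprintf("class %d is not compatible with section %d", c, n))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(state$labels[[n]])))
    stop("mask dimensions do not match the section")
  mask <- mask != 0
  if (any(!is.na(state$labels[[n]]) & mask))
    stop("mask overlaps an existing annotation in this section")
  state$labels[[n]][mask] <- as.integer(c)
  state$A[n, as.character(c)] <- 1L
  state$implied[n] <- length(setdiff(cn, c)) == 1L
  state
}

#' Bootstrap an annotation state from initial masks
#'
#' Builds the initial state required before active learning: at least one
#' annotated mask per class somewhere in the stack.
#'
#' @param masks a list of records `list(n =, c =, mask =)` applied in order.
#' @param dims,bounds,catalog as in [annotation_state()].
#' @return An `annotation_state`.
#' @export
build_initial_state <- function(masks, dims, bounds, catalog) {
  state <- annotation_state(dims, bounds, catalog)
  for (m in masks) state <- apply_annotation(state, m$n, m$c, m$mask)
  missing <- catalog$class_ids[colSums(state$A) == 0L]
  if (length(missing) > 0)
    stop(sprintf("bootstrap requires >= 1 annotation per class; missing: %s",
                 paste(missing, collapse = ", ")))
  state
}

#' Annotated mask of a (section, class) pair
#' @param state an [annotation_state()]. @param n section. @param c class id.
#' @return logical matrix (all-`FALSE` when the pair is annotated but the
#'   structure is absent).
#' @export
annotated_mask <- function(state, n, c) {
  !is.na(state$labels[[n]]) & state$labels[[n]] == c
}

#' @export
print.annotation_state <- function(x, ...) {
  cat(sprintf("<annotation_state> %d section(s), %d class(es), %d annotation(s)\n",
              x$n_sections, ncol(x$A), sum(x$A)))
  invisible(x)
}
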