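# reading/writing stacks, label maps, annotation state and query logs.
# images go through png/tiff; labels are stored as 8-bit indexed pages
# (pixel value = class id), state metadata as JSON, logs as CSV.

read_page <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: %s", path)))
  flatten_channels(img)
}

# collapse RGB(A) to grayscale by averaging colour channels
flatten_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  as.matrix(img)
}

stack_files <- function(path) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  sort(files)
}

#' Read an image stack from disk
#'
#' Accepts a directory of PNG/TIFF files (sections ordered by file name) or
#' a single multi-page TIFF. Each section is min-max rescaled to \[0, 1\];
#' RGB images are averaged to grayscale.
#'
#' @param path directory or multi-page TIFF file.
#' @return An [image_stack()].
#' @export
load_image_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such path: %s", path))
  if (dir.exists(path)) {
    files <- stack_files(path)
    if (length(files) == 0L) stop(sprintf("no PNG/TIFF sections in %s", path))
    sections <- lapply(files, read_page)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop(sprintf("no pages in %s", path))
    sections <- lapply(pages, flatten_channels)
  }
  image_stack(sections)
}

#' Write an image stack
#'
#' @param stack an [image_stack()].
#' @param path output: a `.tif`/`.tiff` file name writes one multi-page
#'   TIFF; anything else is treated as a directory of per-section PNGs.
#' @return `path`, invisibly.
#' @export
save_image_stack <- function(stack, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(stack$sections, path, bits.per.sample = 16L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (n in seq_len(stack$n_sections)) {
      png::writePNG(stack$sections[[n]],
                    file.path(path, sprintf("section_%04d.png", n)))
    }
  }
  invisible(path)
}

label_to_page <- function(m) {
  if (max(m) > 255L) stop("more than 256 classes cannot be stored as 8-bit")
  m / 255
}

page_to_label <- function(p) {
  m <- round(flatten_channels(p) * 255)
  storage.mode(m) <- "integer"
  m
}

#' Read a label stack from disk
#'
#' Indexed 8-bit PNG/TIFF pages whose pixel values are 0-based class ids,
#' either a directory of per-section files or one multi-page TIFF. Every
#' value is validated against the catalog; out-of-catalog values are
#' rejected naming the offending section and value.
#'
#' @param path directory or multi-page TIFF.
#' @param catalog a [class_catalog()].
#' @return A [label_stack()].
#' @export
load_label_stack <- function(path, catalog) {
  if (!file.exists(path)) stop(sprintf("no such path: %s", path))
  if (dir.exists(path)) {
    files <- stack_files(path)
    if (length(files) == 0L) stop(sprintf("no label sections in %s", path))
    sections <- lapply(files, function(f) page_to_label(read_page(f) * 1))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sections <- lapply(pages, page_to_label)
  }
  label_stack(sections, catalog)
}

#' Write a label stack as indexed 8-bit pages
#' @param gt a [label_stack()].
#' @param path multi-page `.tif`/`.tiff` file or directory (per-section TIFFs).
#' @return `path`, invisibly.
#' @export
save_label_stack <- function(gt, path) {
  pages <- lapply(gt$sections, label_to_page)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (n in seq_along(pages)) {
      tiff::writeTIFF(pages[[n]],
                      file.path(path, sprintf("labels_%04d.tif", n)),
                      bits.per.sample = 8L)
    }
  }
  invisible(path)
}

#' Serialize an annotation state to a directory
#'
#' Writes `state.json` (annotation matrix A, bounds, catalog, implied
#' flags, section dimensions) plus one indexed TIFF per annotated
#' (section, class) mask. [load_state()] restores the state bit-exactly.
#'
#' @param state an [annotation_state()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    A = unname(state$A),
    bounds = list(first = unname(state$bounds$first),
                  last = unname(state$bounds$last),
                  n_sections = state$bounds$n_sections),
    catalog = list(n_classes = length(state$catalog$class_ids),
                   names = state$catalog$names,
                   background_id = state$catalog$background_id),
    implied = state$implied,
    dims = lapply(state$labels, dim))
  jsonlite::write_json(meta, file.path(path, "state.json"),
                       auto_unbox = TRUE, digits = NA)
  for (n in seq_len(state$n_sections)) {
    for (c in state$catalog$class_ids) {
      if (state$A[n, as.character(c)] == 1L) {
        m <- annotated_mask(state, n, c)
        tiff::writeTIFF(m * 1, file.path(path, sprintf("mask_n%04d_c%03d.tif", n, c)),
                        bits.per.sample = 8L)
      }
    }
  }
  invisible(path)
}

#' Restore an annotation state written by [save_state()]
#' @param path directory written by [save_state()].
#' @return An [annotation_state()].
#' @export
load_state <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "state.json"),
                              simplifyVector = TRUE)
  catalog <- class_catalog(meta$catalog$n_classes, meta$catalog$names,
                           meta$catalog$background_id)
  bounds <- weak_bounds(meta$bounds$first, meta$bounds$last,
                        meta$bounds$n_sections, catalog)
  dims <- lapply(seq_len(nrow(meta$A)), function(n) unlist(meta$dims[n, ]))
  state <- annotation_state(dims, bounds, catalog)
  A <- matrix(as.integer(meta$A), nrow = nrow(meta$A))
  # replay annotations; apply_annotation re-derives Cn/implied bookkeeping
  for (n in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (A[n, j] == 1L) {
        c <- catalog$class_ids[j]
        f <- file.path(path, sprintf("mask_n%04d_c%03d.tif", n, c))
        mask <- flatten_channels(tiff::readTIFF(f)) > 0.5
        state <- apply_annotation(state, n, c, mask)
      }
    }
  }
  state$implied <- as.logical(meta$implied)
  state
}

query_log_columns <- c("t", "section", "class", "cost",
                       "cumulative_cost", "mean_dice")

#' Write a query log as CSV
#'
#' Fixed header `t,section,class,cost,cumulative_cost,mean_dice`.
#'
#' @param log a tibble with the query-log columns.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
save_log <- function(log, path) {
  log <- as.data.frame(log)[, query_log_columns, drop = FALSE]
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a query log written by [save_log()]
#' @param path CSV file.
#' @return A tibble with columns `t,section,class,cost,cumulative_cost,mean_dice`.
#' @export
load_log <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), query_log_columns))
    stop("not a query log: unexpected columns")
  tibble::as_tibble(df)
}
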