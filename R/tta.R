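#' The 14-view test-time-augmentation crop scheme
#'
#' Deterministic multi-view evaluation geometry: the full image, a central
#' crop covering 80% of width and height, a central 60% crop, four 60%
#' crops anchored flush to the corners, and the horizontal mirror of each of
#' those seven views — 14 views in total. Percentages are fractions of
#' width and height (not area). Each spec is a fractional box, so the same
#' scheme applies to any image size via [crop_pixels()].
#'
#' @return list of 14 `crop_spec` objects, each with fields `box`
#'   (x0, y0, x1, y1 as fractions of width/height), `mirrored`, and `id`.
#' @export
tta_crop_specs <- function() {
  boxes <- list(
    full        = c(0.0, 0.0, 1.0, 1.0),
    center80    = c(0.1, 0.1, 0.9, 0.9),
    center60    = c(0.2, 0.2, 0.8, 0.8),
    topleft60   = c(0.0, 0.0, 0.6, 0.6),
    topright60  = c(0.4, 0.0, 1.0, 0.6),
    bottomleft60  = c(0.0, 0.4, 0.6, 1.0),
    bottomright60 = c(0.4, 0.4, 1.0, 1.0))
  specs <- list()
  for (mirrored in c(FALSE, TRUE)) {
    for (nm in names(boxes)) {
      id <- if (mirrored) paste0(nm, "_mirror") else nm
      specs[[id]] <- crop_spec(boxes[[nm]], mirrored, id)
    }
  }
  specs
}

#' Construct a single crop specification
#' @param box numeric (x0, y0, x1, y1), fractions of image width/height.
#' @param mirrored logical: horizontally flip the crop.
#' @param id optional view identifier.
#' @return object of class `crop_spec`.
#' @export
crop_spec <- function(box, mirrored = FALSE, id = NULL) {
  box <- as.numeric(box)
  if (length(box) != 4L || anyNA(box))
    stop("box must be numeric (x0, y0, x1, y1)")
  if (box[1] < 0 || box[2] < 0 || box[3] > 1 || box[4] > 1 ||
      box[1] >= box[3] || box[2] >= box[4])
    stop("box must satisfy 0 <= x0 < x1 <= 1 and 0 <= y0 < y1 <= 1")
  structure(list(box = stats::setNames(box, c("x0", "y0", "x1", "y1")),
                 mirrored = isTRUE(mirrored),
                 id = id),
            class = "crop_spec")
}

#' @export
print.crop_spec <- function(x, ...) {
  cat(sprintf("crop_spec %s: [%.2f, %.2f, %.2f, %.2f]%s\n",
              if (is.null(x$id)) "" else x$id,
              x$box[1], x$box[2], x$box[3], x$box[4],
              if (x$mirrored) " (mirrored)" else ""))
  invisible(x)
}

# round half away from zero: symmetric for centered crops, unlike round()
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Realize a fractional crop on a concrete image size
#'
#' Converts a fractional [crop_spec()] box to half-open integer pixel
#' coordinates on a width x height image. Edges are rounded half away from
#' zero, which keeps centered crops symmetric.
#'
#' @param spec a [crop_spec()].
#' @param width,height image size in pixels (>= 1).
#' @return integer vector (left, top, right, bottom), half-open:
#'   pixel columns left..right-1, rows top..bottom-1.
#' @export
crop_pixels <- function(spec, width, height) {
  stopifnot(inherits(spec, "crop_spec"), width >= 1, height >= 1)
  b <- spec$box
  px <- c(left   = round_half_away(b[["x0"]] * width),
          top    = round_half_away(b[["y0"]] * height),
          right  = round_half_away(b[["x1"]] * width),
          bottom = round_half_away(b[["y1"]] * height))
  if (px[["right"]] <= px[["left"]] || px[["bottom"]] <= px[["top"]])
    stop("degenerate crop: box ", spec$id, " collapses on a ",
         width, "x", height, " image")
  stats::setNames(as.integer(px), names(px))
}

#' Apply a crop spec to a pixel array
#'
#' Thin utility realizing a [crop_spec()] on an image stored as a matrix
#' (grayscale) or H x W x C array: extracts the pixel box and, if the spec
#' is mirrored, flips it left-right. Resizing/interpolation for network
#' input is deliberately left to the caller.
#'
#' @param img matrix or 3-d array indexed (row, column(, channel)).
#' @param spec a [crop_spec()].
#' @return cropped (and possibly mirrored) array of the same kind.
#' @export
crop_image <- function(img, spec) {
  d <- dim(img)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("img must be a matrix or an H x W x C array")
  px <- crop_pixels(spec, width = d[2L], height = d[1L])
  rows <- (px[["top"]] + 1L):px[["bottom"]]
  cols <- (px[["left"]] + 1L):px[["right"]]
  if (spec$mirrored) cols <- rev(cols)
  if (length(d) == 2L) img[rows, cols, drop = FALSE]
  else img[rows, cols, , drop = FALSE]
}

check_stack <- function(stack) {
  if (!is.list(stack) || !length(stack))
    stop("stack must be a non-empty list of posterior matrices")
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("stack members have mismatched shapes")
  cn <- lapply(stack, colnames)
  if (!all(vapply(cn, identical, logical(1), cn[[1L]])))
    stop("stack members have mismatched species columns")
  stack
}

#' Pool a prediction stack by averaging (sum pooling)
#'
#' Elementwise mean of the posterior matrices across views and/or ensemble
#' members, row-renormalized. Averaging and summing-then-normalizing are
#' identical because row normalization is scale invariant.
#'
#' @param stack list of aligned N x K posterior matrices (same observations
#'   and species order), e.g. one per test-time view or per model.
#' @param space optional [label_space()]; inferred from colnames if absent.
#' @return pooled `posterior_matrix`.
#' @export
pool_sum <- function(stack, space = NULL) {
  stack <- check_stack(stack)
  if (is.null(space)) space <- label_space(colnames(stack[[1L]]))
  m <- Reduce(`+`, lapply(stack, unclass)) / length(stack)
  posterior_matrix(m, space, observation_ids = rownames(stack[[1L]]))
}

#' Pool a prediction stack by majority top-1 vote (mode pooling)
#'
#' Each stack member votes its arg-max species for every observation; the
#' prediction is the most frequent vote. Ties are broken by the larger
#' probability summed over the whole stack, then by species order — a
#' deterministic rule using the available evidence.
#'
#' @inheritParams pool_sum
#' @return list with `prediction` (character vector, one species per
#'   observation) and `votes` (N x K integer matrix of vote tallies).
#' @export
pool_mode <- function(stack, space = NULL) {
  stack <- check_stack(stack)
  if (is.null(space)) space <- label_space(colnames(stack[[1L]]))
  space <- as_label_space(space)
  n <- nrow(stack[[1L]])
  votes <- matrix(0L, n, space$K, dimnames = list(rownames(stack[[1L]]),
                                                  space$species))
  for (m in stack) {
    top <- max.col(unclass(m), ties.method = "first")
    votes[cbind(seq_len(n), top)] <- votes[cbind(seq_len(n), top)] + 1L
  }
  total <- Reduce(`+`, lapply(stack, unclass))
  pred <- vapply(seq_len(n), function(i) {
    cand <- which(votes[i, ] == max(votes[i, ]))
    if (length(cand) > 1L) {
      best <- cand[total[i, cand] == max(total[i, cand])]
      cand <- best  # remaining ties fall to species order via [1]
    }
    space$species[cand[1L]]
  }, character(1))
  list(prediction = pred, votes = votes)
}
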