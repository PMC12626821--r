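# Dataset conventions: RGB images as [H, W, 3] arrays in [0, 1]; masks as
# integer [H, W] matrices of 0-based class indices, stored on disk as
# single-channel 8-bit PNGs whose pixel values are the indices. LabelMe-style
# polygon JSON is accepted as an alternative annotation input.

#' The facial-lesion label schema
#'
#' Ordered class names with 0-based contiguous indices: BACKGROUND (0),
#' ET forehead (1), HHB melasma lesion (2), XB chin (3), LF left face (4),
#' RF right face (5).
#'
#' @return named integer vector mapping class name to index.
#' @export
label_schema <- function() {
  c(BACKGROUND = 0L, ET = 1L, HHB = 2L, XB = 3L, LF = 4L, RF = 5L)
}

#' Rasterize labeled polygons into a class mask
#'
#' Pixels whose centers fall inside a polygon (even-odd rule; pixel `(i, j)`
#' has center `(x, y) = (j - 0.5, i - 0.5)` with 1-based `i, j`, so integer
#' polygon coordinates sit on pixel corners) receive the polygon's class
#' index. Later polygons overwrite earlier ones; pixels outside every polygon
#' are BACKGROUND.
#'
#' @param polygons list of `list(label = "HHB", points = <n x 2 matrix of
#'   (x, y) vertices>)`.
#' @param size image size in pixels (square) or `c(H, W)`.
#' @param schema label schema (name -> index).
#' @return integer `[H, W]` mask.
#' @export
rasterize_polygons <- function(polygons, size, schema = label_schema()) {
  if (length(size) == 1L) size <- c(size, size)
  mask <- matrix(0L, size[1], size[2])
  for (pg in polygons) {
    if (!pg$label %in% names(schema))
      abort_validation(sprintf("unknown class name '%s'", pg$label))
    pts <- pg$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    pts <- matrix(as.numeric(pts), ncol = 2L)
    inside <- polygon_mask(pts, size[1], size[2])
    mask[inside] <- schema[[pg$label]]
  }
  mask
}

# even-odd crossing test over the pixel-center grid, vectorized per edge
polygon_mask <- function(pts, H, W) {
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  jmin <- max(1L, floor(xr[1] + 0.5)); jmax <- min(W, ceiling(xr[2] + 0.5))
  imin <- max(1L, floor(yr[1] + 0.5)); imax <- min(H, ceiling(yr[2] + 0.5))
  out <- matrix(FALSE, H, W)
  if (jmin > jmax || imin > imax) return(out)
  cx <- (jmin:jmax) - 0.5
  cy <- (imin:imax) - 0.5
  px <- outer(cy * 0, cx, "+")     # [ni, nj] of x centers
  py <- outer(cy, cx * 0, "+")
  crossings <- matrix(0L, length(cy), length(cx))
  n <- nrow(pts)
  for (e in seq_len(n)) {
    x1 <- pts[e, 1]; y1 <- pts[e, 2]
    x2 <- pts[e %% n + 1L, 1]; y2 <- pts[e %% n + 1L, 2]
    if (y1 == y2) next
    cond <- ((py >= pmin(y1, y2)) & (py < pmax(y1, y2)))
    xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
    crossings <- crossings + (cond & (px < xint))
  }
  out[imin:imax, jmin:jmax] <- (crossings %% 2L) == 1L
  out
}

#' Read a LabelMe-style polygon annotation file
#'
#' Reads `shapes[].label` and `shapes[].points` from a LabelMe JSON file and
#' rasterizes the polygons.
#'
#' @param path JSON file path.
#' @param size image size (square pixels or `c(H, W)`).
#' @param schema label schema.
#' @return integer `[H, W]` mask.
#' @export
read_labelme_mask <- function(path, size, schema = label_schema()) {
  js <- jsonlite::read_json(path)
  polys <- lapply(js$shapes, function(s)
    list(label = s$label,
         points = do.call(rbind, lapply(s$points, function(p) unlist(p)))))
  rasterize_polygons(polys, size, schema)
}

#' Write / read an image or indexed mask as PNG
#'
#' Masks are stored as single-channel 8-bit PNGs whose gray levels are the
#' class indices; images as RGB PNGs in `[0, 1]`.
#'
#' @param mask integer `[H, W]` matrix.
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param path file path.
#' @return the read object, or the path invisibly for writers.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname write_mask_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_image_png <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
  im[, , 1:3, drop = FALSE]
}

#' Load an image/mask dataset from disk
#'
#' Expects `root/images/<name>.png` and `root/masks/<name>.png` matched by
#' basename; each pair is validated for equal spatial size and legal labels.
#' Items are ordered deterministically by basename.
#'
#' @param root dataset directory.
#' @param schema label schema; mask values must be a subset of its indices.
#' @return a `seg_dataset`: list of `list(name, image, mask)` with the schema
#'   attached.
#' @export
load_dataset <- function(root, schema = label_schema()) {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L)
    abort_validation(sprintf("no PNG images found under %s", img_dir))
  items <- lapply(files, function(f) {
    mpath <- file.path(msk_dir, f)
    if (!file.exists(mpath))
      abort_validation(sprintf("missing mask for image '%s'", f))
    image <- read_image_png(file.path(img_dir, f))
    mask <- read_mask_png(mpath)
    if (!identical(dim(mask), dim(image)[1:2]))
      abort_validation(sprintf("image/mask size mismatch for '%s'", f))
    bad <- setdiff(unique(as.vector(mask)), unname(schema))
    if (length(bad) > 0L)
      abort_validation(sprintf("mask '%s' contains illegal label(s) %s",
                               f, paste(bad, collapse = ", ")))
    list(name = sub("\\.png$", "", f), image = image, mask = mask)
  })
  structure(items, class = "seg_dataset", schema = schema)
}

#' Write a dataset of (image, mask) pairs to disk
#'
#' @param items list of `list(name, image, mask)`.
#' @param root target directory (`images/` and `masks/` are created).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(items, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (it in items) {
    write_image_png(it$image, file.path(root, "images", paste0(it$name, ".png")))
    write_mask_png(it$mask, file.path(root, "masks", paste0(it$name, ".png")))
  }
  invisible(root)
}

#' Split a dataset 8:1:1 into train/validation/test
#'
#' Validation and test each receive `floor(n/10)` items, training the rest
#' (for n = 501 this is the 401/50/50 partition); membership is a seeded
#' shuffle, so the same `n` and `seed` always produce the same assignment.
#'
#' @param n item count (>= 10).
#' @param seed integer seed.
#' @return a `split_assignment`: list with integer index vectors `train`,
#'   `val`, `test` and the seed.
#' @export
split_dataset <- function(n, seed = 1L) {
  if (n < 10L) abort_validation("need at least 10 items for an 8:1:1 split")
  n_val <- n %/% 10L
  n_test <- n %/% 10L
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  structure(list(train = sort(ord[seq_len(n - n_val - n_test)]),
                 val = sort(ord[n - n_val - n_test + seq_len(n_val)]),
                 test = sort(ord[n - n_test + seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Dataset manifest as a tibble
#'
#' @param items a `seg_dataset` (or list with `name` fields).
#' @param split a [split_dataset()] assignment.
#' @return tibble with columns `basename`, `split`.
#' @export
split_manifest <- function(items, split) {
  nm <- vapply(items, function(x) x$name, character(1))
  lab <- rep("train", length(nm))
  lab[split$val] <- "val"
  lab[split$test] <- "test"
  tibble::tibble(basename = nm, split = lab)
}
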