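# Synthetic facial-lesion scene generator. Emulates the visual challenges of
# clinical melasma photographs -- low-contrast brown patches with irregular,
# blurred boundaries on facial skin, illumination gradients and specular
# highlights -- on a face-like scene whose mask partitions the face ellipse
# into forehead (ET), chin (XB), left/right cheek areas (LF/RF), with melasma
# lesions (HHB) as thresholded-smoothed-noise blobs strictly inside the face.

#' Scene specification for the synthetic generator
#'
#' @param image_size square size in pixels (>= 32).
#' @param lesion_count integer range (length-2) of lesion blob counts.
#' @param lesion_contrast mean intensity offset of lesions versus surrounding
#'   skin, in image units on `[0, 1]`. Melasma patches are darker brown than
#'   the surrounding skin but only mildly so; default 0.12.
#' @param boundary_blur Gaussian sigma (pixels) applied to the lesion alpha
#'   in the image, softening lesion edges; the mask keeps the un-blurred
#'   support.
#' @param illumination_gradient maximum relative brightness slope across the
#'   face (0 disables).
#' @param specular_spots number of bright specular highlights (image only).
#' @param noise_sd additive Gaussian noise scale.
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 128L, lesion_count = c(2L, 5L),
                       lesion_contrast = 0.12, boundary_blur = 1.5,
                       illumination_gradient = 0.15, specular_spots = 2L,
                       noise_sd = 0.02, seed = 1L) {
  if (image_size < 32L) abort_validation("image_size must be at least 32")
  if (length(lesion_count) == 1L) lesion_count <- rep(lesion_count, 2L)
  if (lesion_contrast < 0 || lesion_contrast > 0.5)
    abort_validation("lesion_contrast must keep lesions in a valid intensity range")
  structure(list(image_size = as.integer(image_size),
                 lesion_count = as.integer(lesion_count),
                 lesion_contrast = lesion_contrast,
                 boundary_blur = boundary_blur,
                 illumination_gradient = illumination_gradient,
                 specular_spots = as.integer(specular_spots),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate one synthetic facial-lesion scene
#'
#' @param spec a [scene_spec()].
#' @return `list(image = [S, S, 3] array in [0, 1], mask = integer [S, S]
#'   matrix of schema labels)`.
#' @export
synth_face_scene <- function(spec) {
  withr::with_seed(spec$seed, synth_scene_impl(spec))
}

synth_scene_impl <- function(spec) {
  S <- spec$image_size
  sch <- label_schema()
  yy <- matrix(seq_len(S) - 0.5, S, S)          # row coordinate (down)
  xx <- t(yy)                                   # column coordinate (right)
  cx <- S / 2 + stats::runif(1, -0.02, 0.02) * S
  cy <- S / 2 + stats::runif(1, -0.02, 0.02) * S
  a <- 0.36 * S * stats::runif(1, 0.95, 1.05)   # horizontal semi-axis
  b <- 0.45 * S * stats::runif(1, 0.95, 1.05)   # vertical semi-axis
  e <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2
  face <- e <= 1
  mask <- matrix(sch[["BACKGROUND"]], S, S)
  top_cut <- cy - 0.45 * b                      # forehead band
  bot_cut <- cy + 0.55 * b                      # chin band
  mask[face & yy < top_cut] <- sch[["ET"]]
  mask[face & yy >= bot_cut] <- sch[["XB"]]
  mid <- face & yy >= top_cut & yy < bot_cut
  mask[mid & xx < cx] <- sch[["LF"]]
  mask[mid & xx >= cx] <- sch[["RF"]]

  # lesions: thresholded smoothed noise blobs strictly inside the face
  inner <- e <= 0.85
  n_lesions <- if (spec$lesion_count[2] > spec$lesion_count[1])
    sample(spec$lesion_count[1]:spec$lesion_count[2], 1L) else spec$lesion_count[1]
  lesion <- matrix(FALSE, S, S)
  if (n_lesions > 0L) {
    cand <- which(inner)
    for (i in seq_len(n_lesions)) {
      placed <- FALSE
      for (try in 1:20) {
        ctr <- cand[sample.int(length(cand), 1L)]
        ci <- (ctr - 1L) %% S + 1L
        cj <- (ctr - 1L) %/% S + 1L
        r <- stats::runif(1, 0.05, 0.11) * S     # patch radius in pixels
        field <- blur2d(matrix(stats::rnorm(S * S), S, S), r / 2)
        field <- field / max(abs(field))
        dist2 <- (yy - ci + 0.5)^2 + (xx - cj + 0.5)^2
        bump <- exp(-dist2 / (2 * r^2))
        # half-max threshold of the irregularly modulated bump: patch-scale
        # blobs with ragged borders, area ~ r^2
        blob <- (bump * (1 + 0.6 * field)) > 0.5
        blob <- blob & inner
        if (sum(blob) >= 8L) { lesion <- lesion | blob; placed <- TRUE; break }
      }
      if (!placed)
        abort_validation("lesion placement failed for this scene specification")
    }
  }
  mask[lesion] <- sch[["HHB"]]

  # image: skin base color, lesion recoloring, illumination, speculars, noise
  skin <- c(0.80, 0.62, 0.52) * stats::runif(1, 0.95, 1.05)
  bg <- c(0.10, 0.10, 0.12)
  img <- array(0, c(S, S, 3L))
  alpha <- blur2d(lesion * 1.0, spec$boundary_blur)
  alpha <- pmin(alpha, 1)
  # channel weighting of the brown shift, normalized so the mean intensity
  # offset over (R, G, B) equals lesion_contrast
  wch <- c(0.6, 1.1, 1.3); wch <- wch / mean(wch)
  for (ch in 1:3) {
    plane <- matrix(bg[ch], S, S)
    plane[face] <- skin[ch]
    plane <- plane - spec$lesion_contrast * wch[ch] * alpha
    img[, , ch] <- plane
  }
  if (spec$illumination_gradient > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    g <- spec$illumination_gradient
    ramp <- 1 + g * (((xx - cx) * cos(th) + (yy - cy) * sin(th)) / S)
    img <- img * as.vector(ramp)
  }
  if (spec$specular_spots > 0L) {
    cand <- which(face)
    for (i in seq_len(spec$specular_spots)) {
      ctr <- cand[sample.int(length(cand), 1L)]
      ci <- (ctr - 1L) %% S + 1L
      cj <- (ctr - 1L) %/% S + 1L
      r <- stats::runif(1, 0.015, 0.035) * S
      d2 <- (yy - ci + 0.5)^2 + (xx - cj + 0.5)^2
      img <- img + as.vector(0.35 * exp(-d2 / (2 * r^2)))
    }
  }
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a synthetic dataset
#'
#' @param n number of scenes.
#' @param spec base [scene_spec()]; scene `i` uses seed `spec$seed + i - 1`.
#' @return a `seg_dataset` list of `list(name, image, mask)`.
#' @export
synth_dataset <- function(n, spec = scene_spec()) {
  items <- lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- spec$seed + i - 1L
    sc <- synth_face_scene(sp)
    list(name = sprintf("scene_%04d", i), image = sc$image, mask = sc$mask)
  })
  structure(items, class = "seg_dataset", schema = label_schema())
}

#' Random flip / crop augmentation for an image/mask pair
#'
#' Horizontal and vertical flips each with probability 0.5, then a random
#' crop with relative scale drawn from `[0.7, 1]`, resized back to the
#' original size (bilinear for the image, nearest-neighbour for the mask).
#' Image and mask receive the identical geometric transform.
#'
#' @param image `[H, W, 3]` array.
#' @param mask integer `[H, W]` matrix.
#' @param seed integer seed; the draw is deterministic given it.
#' @param flips,crop logical toggles for the two transform families.
#' @return `list(image, mask)`.
#' @export
augment <- function(image, mask, seed = 1L, flips = TRUE, crop = TRUE) {
  withr::with_seed(as.integer(seed), {
    H <- dim(image)[1]; W <- dim(image)[2]
    if (flips && stats::runif(1) < 0.5) {       # horizontal flip
      image <- image[, W:1, , drop = FALSE]
      mask <- mask[, W:1, drop = FALSE]
    }
    if (flips && stats::runif(1) < 0.5) {       # vertical flip
      image <- image[H:1, , , drop = FALSE]
      mask <- mask[H:1, , drop = FALSE]
    }
    if (crop) {
      sc <- stats::runif(1, 0.7, 1)
      ch <- max(1L, round(H * sc)); cw <- max(1L, round(W * sc))
      i0 <- sample.int(H - ch + 1L, 1L) - 1L
      j0 <- sample.int(W - cw + 1L, 1L) - 1L
      sub_img <- image[i0 + seq_len(ch), j0 + seq_len(cw), , drop = FALSE]
      sub_msk <- mask[i0 + seq_len(ch), j0 + seq_len(cw), drop = FALSE]
      image <- bilinear_resize(sub_img, H, W)
      mask <- nearest_resize(sub_msk, H, W)
    }
    list(image = image, mask = mask)
  })
}
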