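# Dataset plumbing: polygon rasterization, PNG round trips, 8:1:1 split,
# augmentation, and the synthetic facial-lesion scene generator.

test_that("axis-aligned square polygons rasterize to exact pixel blocks", {
  poly <- list(list(label = "HHB", points = rbind(c(2, 2), c(4, 2), c(4, 4), c(2, 4))))
  mask <- rasterize_polygons(poly, 8)
  expect_equal(sum(mask == 2L), 4L)
  expect_true(all(mask[3:4, 3:4] == 2L))
  # empty polygon list: all background
  expect_true(all(rasterize_polygons(list(), 8) == 0L))
  # later polygons overwrite earlier ones
  p2 <- list(
    list(label = "LF", points = rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6))),
    list(label = "RF", points = rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6))))
  m2 <- rasterize_polygons(p2, 8)
  expect_equal(m2[2, 2], 4L)
  expect_equal(m2[4, 4], 5L)
  expect_error(rasterize_polygons(list(list(label = "NOPE",
                                            points = rbind(c(0, 0), c(1, 0), c(1, 1)))), 8),
               class = "melseg_error_validation")
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  withr::with_seed(5, {
    for (rep in 1:5) {
      k <- sample(3:7, 1)
      ang <- sort(stats::runif(k, 0, 2 * pi))
      r <- stats::runif(k, 3, 7)
      pts <- cbind(8 + r * cos(ang), 8 + r * sin(ang))   # star-shaped, no self-crossings
      mask <- rasterize_polygons(list(list(label = "HHB", points = pts)), 16)
      centers <- expand.grid(i = 1:16, j = 1:16)
      inside <- mgcv::in.out(rbind(pts, pts[1, ]),
                             cbind(centers$j - 0.5, centers$i - 0.5))
      ours <- mask[cbind(centers$i, centers$j)] == 2L
      expect_equal(ours, as.vector(inside))
    }
  })
})

test_that("LabelMe-style polygon JSON loads and rasterizes", {
  js <- list(shapes = list(
    list(label = "ET", points = list(list(1, 1), list(5, 1), list(5, 3), list(1, 3))),
    list(label = "HHB", points = list(list(2, 2), list(4, 2), list(4, 4), list(2, 4)))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(js, path, auto_unbox = TRUE)
  mask <- read_labelme_mask(path, 8)
  expect_equal(mask[2, 2], 1L)       # forehead polygon
  expect_equal(mask[3, 3], 2L)       # lesion overwrites
})

test_that("split sizes follow the 8:1:1 rule and are reproducible", {
  s <- split_dataset(501, seed = 1)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 401L, val = 50L, test = 50L))
  s10 <- split_dataset(10, seed = 3)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  # disjoint and exhaustive
  all_idx <- sort(c(s$train, s$val, s$test))
  expect_identical(all_idx, 1:501)
  # determinism and seed sensitivity
  expect_identical(split_dataset(100, seed = 7), split_dataset(100, seed = 7))
  s_a <- split_dataset(100, seed = 7); s_b <- split_dataset(100, seed = 8)
  expect_false(identical(s_a$test, s_b$test))
  expect_equal(length(s_b$val), 10L)
  expect_error(split_dataset(9), class = "melseg_error_validation")
})

test_that("augmentation applies identical geometry to image and mask", {
  sc <- synth_face_scene(scene_spec(image_size = 64, seed = 3))
  # double horizontal flip restores the original exactly
  f1 <- sc$image[, 64:1, , drop = FALSE]
  expect_identical(f1[, 64:1, , drop = FALSE], sc$image)
  # forced identity: crop disabled, flips disabled
  out <- augment(sc$image, sc$mask, seed = 1, flips = FALSE, crop = FALSE)
  expect_identical(out$image, sc$image)
  expect_identical(out$mask, sc$mask)
  # a pure flip permutes pixels: class histogram is unchanged
  for (seed in 1:8) {
    fl <- augment(sc$image, sc$mask, seed = seed, crop = FALSE)
    expect_equal(tabulate(fl$mask + 1L, 6), tabulate(sc$mask + 1L, 6))
  }
  # flips keep per-class centroids consistent (mirrored coordinates)
  fl <- withr::with_seed(1, {
    list(image = sc$image[, 64:1, , drop = FALSE], mask = sc$mask[, 64:1, drop = FALSE])
  })
  for (cls in c(1L, 4L, 5L)) {
    w <- which(sc$mask == cls, arr.ind = TRUE)
    wf <- which(fl$mask == cls, arr.ind = TRUE)
    expect_equal(mean(wf[, 2]), 65 - mean(w[, 2]), tolerance = 1e-9)
    expect_equal(mean(wf[, 1]), mean(w[, 1]), tolerance = 1e-9)
  }
  # cropping keeps the mask label set inside the schema
  cr <- augment(sc$image, sc$mask, seed = 5)
  expect_true(all(cr$mask %in% 0:5))
  expect_identical(dim(cr$image), dim(sc$image))
  # same seed, same draw
  expect_identical(augment(sc$image, sc$mask, seed = 5), cr)
})

test_that("synthetic scenes are deterministic, schema-bounded and face-structured", {
  spec <- scene_spec(image_size = 64, seed = 11)
  a <- synth_face_scene(spec)
  b <- synth_face_scene(spec)
  expect_identical(a, b)
  c2 <- synth_face_scene(scene_spec(image_size = 64, seed = 12))
  expect_false(identical(a$mask, c2$mask))
  expect_true(all(a$mask %in% 0:5))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # zero lesion count: no HHB pixels
  z <- synth_face_scene(scene_spec(image_size = 64, lesion_count = c(0, 0), seed = 3))
  expect_equal(sum(z$mask == 2L), 0L)
  # lesions lie strictly inside the face (never touch BACKGROUND-adjacent border)
  les <- which(a$mask == 2L, arr.ind = TRUE)
  expect_gt(nrow(les), 0)
  for (k in seq_len(nrow(les))) {
    i <- les[k, 1]; j <- les[k, 2]
    nb <- c(a$mask[max(i - 1, 1), j], a$mask[min(i + 1, 64), j],
            a$mask[i, max(j - 1, 1)], a$mask[i, min(j + 1, 64)])
    expect_true(all(nb != 0L))
  }
})

test_that("zero-contrast lesions are invisible up to noise", {
  spec <- scene_spec(image_size = 128, lesion_count = c(4, 4), lesion_contrast = 0,
                     boundary_blur = 0, illumination_gradient = 0,
                     specular_spots = 0, noise_sd = 0.02, seed = 21)
  sc <- synth_face_scene(spec)
  inside <- sc$mask == 2L
  outside <- matrix(sc$mask %in% c(1L, 3L, 4L, 5L), nrow(sc$mask))
  n_in <- sum(inside)
  expect_gte(n_in, 100)
  lum_in <- mean(sc$image[cbind(which(inside, arr.ind = TRUE), 2)])
  lum_out <- mean(sc$image[cbind(which(outside, arr.ind = TRUE), 2)])
  expect_lt(abs(lum_in - lum_out), 3 * spec$noise_sd / sqrt(n_in))
})

test_that("datasets round-trip through PNG images and indexed masks", {
  ds <- synth_dataset(3, scene_spec(image_size = 32, seed = 5))
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  back <- load_dataset(root)
  expect_length(back, 3)
  expect_identical(vapply(back, `[[`, "", "name"),
                   vapply(ds, `[[`, "", "name"))
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, ds[[i]]$mask)          # masks exact
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 255)  # 8-bit images
  }
  # missing mask and illegal labels are reported per file
  file.remove(file.path(root, "masks", "scene_0002.png"))
  expect_error(load_dataset(root), class = "melseg_error_validation",
               regexp = "scene_0002")
  write_mask_png(ds[[2]]$mask, file.path(root, "masks", "scene_0002.png"))
  bad <- ds[[1]]$mask; bad[1, 1] <- 7L
  write_mask_png(bad, file.path(root, "masks", "scene_0001.png"))
  expect_error(load_dataset(root), class = "melseg_error_validation",
               regexp = "scene_0001")
})

test_that("split manifests label items by membership", {
  ds <- synth_dataset(10, scene_spec(image_size = 32, seed = 9))
  sp <- split_dataset(10, seed = 2)
  mf <- split_manifest(ds, sp)
  expect_equal(nrow(mf), 10)
  expect_equal(sum(mf$split == "train"), 8)
  expect_equal(sum(mf$split == "val"), 1)
  expect_equal(sum(mf$split == "test"), 1)
})
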