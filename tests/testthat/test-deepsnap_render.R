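test_that("angle enumeration matches the closed-form grid", {
  a27 <- enumerate_angles(c(145, 145, 145))
  expect_equal(nrow(a27), 27L)
  expect_equal(unique(a27[, 1L]), c(0, 145, 290))
  expect_equal(nrow(enumerate_angles(c(65, 65, 65))), 216L)
  expect_equal(nrow(enumerate_angles(c(360, 360, 360))), 1L)
  expect_equal(enumerate_angles(c(360, 360, 360))[1L, ],
               c(angle_x = 0, angle_y = 0, angle_z = 0))
  expect_error(enumerate_angles(c(0, 90, 90)))
  expect_error(enumerate_angles(c(90, 90, 361)))
})

test_that("angle count and ordering hold for random increments", {
  withr::with_seed(42, {
    for (i in 1:20) {
      inc <- stats::runif(3, 1, 360)
      a <- enumerate_angles(inc)
      expect_equal(nrow(a), prod(ceiling(360 / inc)))
      expect_false(any(duplicated(a)))
      # lexicographic order on (x, y, z)
      key <- a[, 1L] * 1e8 + a[, 2L] * 1e2 + a[, 3L] * 1e-4
      expect_true(all(diff(key) > 0))
      expect_true(all(a < 360))
    }
  })
})

test_that("a single atom renders as one centered disk of its element color", {
  co <- data.frame(element = "C", x = 0, y = 0, z = 0)
  img <- render_snapshot(co, c(30, 60, 90), render_params(image_px = 64))
  fg <- which(img[, , 1] + img[, , 2] + img[, , 3] > 0, arr.ind = TRUE)
  expect_gt(nrow(fg), 0)
  expect_equal(unname(colMeans(fg)), c(32.5, 32.5), tolerance = 1)
  # rotation-invariant: a point molecule looks the same from every angle
  img2 <- render_snapshot(co, c(0, 0, 0), render_params(image_px = 64))
  expect_identical(img, img2)
  # grey carbon: equal channels at the brightest pixel
  i <- fg[which.max(img[, , 1][fg]), ]
  expect_equal(img[i[1], i[2], 1], img[i[1], i[2], 2])
})

test_that("rendering is deterministic, translation-invariant and 360-periodic", {
  r <- fx_embedded()[[2L]]
  p <- fx_render_params()
  base <- render_snapshot(r$coords, c(145, 0, 290), p, r$bonds)
  expect_identical(base, render_snapshot(r$coords, c(145, 0, 290), p, r$bonds))

  shifted <- r$coords
  shifted$x <- shifted$x + 11.25
  shifted$y <- shifted$y - 3.875
  shifted$z <- shifted$z + 57.5
  expect_identical(base, render_snapshot(shifted, c(145, 0, 290), p, r$bonds))

  at0 <- render_snapshot(r$coords, c(0, 0, 0), p, r$bonds)
  for (full_turn in list(c(360, 0, 0), c(0, 360, 0), c(0, 0, 360)))
    expect_identical(at0, render_snapshot(r$coords, full_turn, p, r$bonds))
})

test_that("a z-rotation by 90 degrees turns an x-aligned diatomic vertical", {
  co <- data.frame(element = c("C", "C"), x = c(-1.5, 1.5), y = 0, z = 0)
  bonds <- data.frame(from = 1L, to = 2L, order = 1L)
  img <- render_snapshot(co, c(0, 0, 90), render_params(image_px = 96), bonds)
  fg <- which(img[, , 1] + img[, , 2] + img[, , 3] > 0, arr.ind = TRUE)
  # principal axis of the lit pixels: oracle = analytic rotation puts the
  # bond along the image y (row) direction
  cc <- scale(fg, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc))$vectors[, 1L]
  angle_from_vertical <- acos(abs(ev[1L])) * 180 / pi  # row axis = vertical
  expect_lt(angle_from_vertical, 2)
})

test_that("snapshot_compound writes the full angle grid and a faithful manifest", {
  r <- fx_embedded()[[1L]]
  dir <- tempfile(); p <- fx_render_params()
  man <- snapshot_compound(r, p, dir)
  expect_s3_class(man, "snapshot_manifest")
  expect_equal(nrow(man), 27L)
  expect_true(all(file.exists(man$path)))
  expect_equal(as.matrix(man[, c("angle_x", "angle_y", "angle_z")]),
               enumerate_angles(p$angle_increment), ignore_attr = TRUE)
  img <- png::readPNG(man$path[1L])
  expect_equal(dim(img), c(48L, 48L, 3L))

  # identical conformers give bitwise-identical images per angle
  r2 <- r; r2$compound_id <- "TWIN"
  man2 <- snapshot_compound(r2, p, dir)
  h1 <- unname(tools::md5sum(man$path))
  h2 <- unname(tools::md5sum(man2$path))
  expect_identical(h1, h2)
})

test_that("manifest text round-trips with its render parameters", {
  man <- fx_manifest()
  f <- tempfile(fileext = ".tsv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(as.data.frame(back), as.data.frame(man))
  expect_equal(attr(back, "render_params"), attr(man, "render_params"))
})

test_that("degenerate all-coincident coordinates still render", {
  co <- data.frame(element = c("C", "C", "C"), x = 1, y = 1, z = 1)
  img <- suppressMessages(render_snapshot(co, c(0, 0, 0), render_params(image_px = 32)))
  expect_true(any(img > 0))
})
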