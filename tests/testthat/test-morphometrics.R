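# helper: rotate + translate a contour rigidly
rigid <- function(cont, theta = 0, shift = c(0, 0)) {
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  out <- cont
  out$vertices <- sweep(cont$vertices %*% t(R), 2, -shift)
  colnames(out$vertices) <- c("x", "y")
  out
}

test_that("segmentation finds each object on a black background", {
  sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  img <- rasterize_contour(sq, image_size = c(120L, 120L), scale = 60)
  masks <- segment_image(img)
  expect_length(masks, 1L)
  expect_identical(sum(masks[[1]]), sum(img == 1))

  # two disjoint sepals in one image
  two <- matrix(0, 150, 300)
  two[, 1:140] <- rasterize_contour(sepal_contour(2, 1), c(150L, 140L))
  two[, 161:300] <- rasterize_contour(sepal_contour(1.5, 1), c(150L, 140L))
  expect_length(segment_image(two), 2L)

  expect_length(segment_image(matrix(0, 50, 50)), 0L)
})

test_that("mask boundaries enclose the pixel area of the component", {
  sq <- matrix(0, 120, 120)
  sq[11:110, 11:110] <- 1
  cont <- mask_to_contour(sq)
  expect_equal(abs(sepalcv:::shoelace_area(cont$vertices)), 100^2,
               tolerance = 0.02)

  one_px <- matrix(0, 10, 10)
  one_px[5, 5] <- 1
  expect_error(mask_to_contour(one_px), "degenerate")
  expect_error(mask_to_contour(matrix(0, 10, 10)), "empty mask")

  ell <- rasterize_contour(sepal_contour(400, 200, n_vertices = 2048L),
                           image_size = c(450L, 250L), scale = 1)
  cont <- mask_to_contour(ell)
  expect_equal(abs(sepalcv:::shoelace_area(cont$vertices)), pi * 200 * 100,
               tolerance = 0.02)
})

test_that("alignment puts the principal axis vertical", {
  rect <- as_contour(cbind(c(-1, 1, 1, -1), c(-2, -2, 2, 2)))
  tilted <- rigid(rect, theta = 30 * pi / 180, shift = c(3, -7))
  al <- align_contour(tilted)
  expect_equal(diff(range(al$vertices[, 1])), 2, tolerance = 1e-6)
  expect_equal(diff(range(al$vertices[, 2])), 4, tolerance = 1e-6)
  expect_equal(colMeans(al$vertices), c(x = 0, y = 0), tolerance = 1e-9)

  # circle: any rotation is valid, bounding box 2r x 2r regardless
  t <- seq(0, 2 * pi, length.out = 4097)[-1]
  circ <- align_contour(as_contour(cbind(cos(t), sin(t))))
  expect_equal(diff(range(circ$vertices[, 1])), 2, tolerance = 1e-3)
  expect_equal(diff(range(circ$vertices[, 2])), 2, tolerance = 1e-3)

  # idempotence up to axis sign: extents and area are unchanged
  once <- align_contour(tilted)
  twice <- align_contour(once)
  expect_equal(abs(sepalcv:::shoelace_area(twice$vertices)),
               abs(sepalcv:::shoelace_area(once$vertices)), tolerance = 1e-12)
  expect_equal(apply(twice$vertices, 2, range), apply(once$vertices, 2, range),
               tolerance = 1e-9)

  degenerate <- as_contour(cbind(c(0, 1, 2), c(0, 1e-15, 0)))
  expect_error(align_contour(degenerate), "degenerate")
})

test_that("shape parameters match closed forms", {
  sq <- align_contour(as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  expect_equal(unname(unlist(measure_contour(sq))),
               c(1, 1, 1, 1), tolerance = 1e-12)

  rect <- align_contour(as_contour(cbind(c(0, 2, 2, 0), c(0, 0, 4, 4))))
  sp <- measure_contour(rect)
  expect_equal(sp$area, 8)
  expect_equal(sp$length, 4)
  expect_equal(sp$width, 2)
  expect_equal(sp$aspect_ratio, 2)

  ell <- align_contour(sepal_contour(4, 2, n_vertices = 4096L))
  sp <- measure_contour(ell)
  expect_equal(sp$area, pi * 2 * 1, tolerance = 0.001)
  expect_equal(sp$length, 4, tolerance = 0.001)
  expect_equal(sp$width, 2, tolerance = 0.001)
  expect_equal(sp$aspect_ratio, 2, tolerance = 0.001)
})

test_that("measurements are rigid-motion invariant and scale equivariant", {
  set.seed(202)
  for (i in 1:50) {
    L <- runif(1, 1.5, 4)
    W <- runif(1, 0.8, L)
    p <- runif(1, 1.6, 3)
    cont <- sepal_contour(L, W, tip_sharpness = p, n_vertices = 512L,
                          seed = i)
    base_sp <- measure_contour(align_contour(cont))
    # generator ground truth within 1%
    expect_equal(base_sp$length, L, tolerance = 0.01)
    expect_equal(base_sp$width, W, tolerance = 0.01)
    expect_equal(base_sp$aspect_ratio, L / W, tolerance = 0.01)

    moved <- rigid(cont, theta = runif(1, 0, 2 * pi),
                   shift = runif(2, -10, 10))
    moved_sp <- measure_contour(align_contour(moved))
    expect_equal(unname(unlist(moved_sp)), unname(unlist(base_sp)),
                 tolerance = 1e-6)

    s <- runif(1, 0.5, 3)
    scaled <- cont
    scaled$vertices <- cont$vertices * s
    scaled_sp <- measure_contour(align_contour(scaled))
    expect_equal(scaled_sp$area, base_sp$area * s^2, tolerance = 1e-9)
    expect_equal(scaled_sp$length, base_sp$length * s, tolerance = 1e-9)
    expect_equal(scaled_sp$width, base_sp$width * s, tolerance = 1e-9)
    expect_equal(scaled_sp$aspect_ratio, base_sp$aspect_ratio,
                 tolerance = 1e-9)
  }
})

test_that("directories of photographs become measurement tables", {
  dir <- withr::local_tempdir()
  specs <- list(c(12, 6), c(10, 7), c(14, 5))  # true length/width in mm
  for (i in seq_along(specs)) {
    cont <- sepal_contour(specs[[i]][1], specs[[i]][2], n_vertices = 1024L)
    # 0.01 mm/px: 12 mm -> 1200 px
    img <- rasterize_contour(cont, image_size = c(1600L, 900L), scale = 100)
    write_image(img, file.path(dir, sprintf("geno%d.png", i)))
  }
  tab <- measure_images(dir, calibration = 0.01)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$genotype, c("geno1", "geno2", "geno3"))
  expect_equal(tab$length[1], 12, tolerance = 0.005)
  expect_equal(tab$width[1], 6, tolerance = 0.005)
  expect_identical(tab, measure_images(dir, calibration = 0.01))

  # unreadable file is skipped with a warning, not fatal
  writeLines("not a png", file.path(dir, "broken.png"))
  expect_warning(tab2 <- measure_images(dir, calibration = 0.01), "skipping")
  expect_identical(nrow(tab2), 3L)
  expect_identical(basename(attr(tab2, "skipped")), "broken.png")
})
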