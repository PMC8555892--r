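test_that("HSB thresholding follows the window semantics", {
  cw <- cell_hsb_window()
  tw <- tau_hsb_window()
  # all-black image fails the cell brightness window
  black <- array(0, dim = c(8, 8, 3))
  expect_false(any(hsb_threshold(black, cw)))
  # a uniform in-window colour passes everywhere
  inside <- uniform_hsb_image(150, 80, 190)
  expect_true(all(hsb_threshold(inside, cw)))
  expect_false(any(hsb_threshold(inside, tw)))
  # wrapping tau hue window: hue 10 passes, hue 130 fails
  expect_true(all(hsb_threshold(uniform_hsb_image(10, 150, 120), tw)))
  expect_false(any(hsb_threshold(uniform_hsb_image(130, 150, 120), tw)))
  # masks are idempotent: re-thresholding the same image is identical
  slide <- gen_histology_image(seed = 6, width = 128, height = 128,
                               n_cells = 4, n_tau = 1)
  m1 <- hsb_threshold(slide$image, tw)
  m2 <- hsb_threshold(slide$image, tw)
  expect_identical(m1, m2)
  expect_error(hsb_threshold(array(300, dim = c(2, 2, 3)), cw), "8-bit")
  expect_error(hsb_window(c(-1, 10), c(0, 1), c(0, 1)), "within")
})

test_that("cell counting recovers known disk counts", {
  # blank field
  blank <- uniform_hsb_image(0, 0, 250, 64, 64)
  expect_equal(count_cells(blank)$count, 0)
  expect_equal(tau_burden(blank)$cell_count, 0)
  # non-touching disks are counted exactly
  slide <- gen_histology_image(seed = 1, n_cells = 20, n_tau = 0)
  expect_equal(count_cells(slide$image)$count, slide$truth$n_cells)
  # two fused disks are split by the watershed
  pair <- gen_histology_image(seed = 2, width = 128, height = 128,
                              n_cells = 0, n_tau = 0, overlap_pairs = 1)
  expect_equal(count_cells(pair$image)$count, 2)
})

test_that("cell counting is invariant to translation and rotation", {
  slide <- gen_histology_image(seed = 3, width = 200, height = 200,
                               n_cells = 6, n_tau = 0)
  base <- count_cells(slide$image)$count
  rotated <- aperm(slide$image, c(2, 1, 3))[, dim(slide$image)[1]:1, ]
  expect_equal(count_cells(rotated)$count, base)
  shifted <- slide$image
  shifted <- shifted[c(6:200, 1:5), , ]   # cyclic shift, margins are blank
  expect_equal(count_cells(shifted)$count, base)
})

test_that("raising the area cutoff never increases the count", {
  slide <- gen_histology_image(seed = 4, n_cells = 15, n_tau = 0)
  cuts <- c(50, 200, 400, 600)
  counts <- vapply(cuts, function(a) {
    count_cells(slide$image, min_area = a)$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tau burden recovers painted areas and scales with blob count", {
  blank <- uniform_hsb_image(0, 0, 250, 64, 64)
  b0 <- tau_burden(blank)
  expect_equal(b0$tau_area_px, 0L)
  expect_false(b0$burden_defined)
  expect_true(is.na(b0$burden))
  slide <- gen_histology_image(seed = 5, n_cells = 12, n_tau = 3)
  res <- tau_burden(slide$image)
  expect_equal(res$cell_count, slide$truth$n_cells)
  expect_equal(res$tau_area_px, slide$truth$tau_area_px,
               tolerance = 0.02)
  expect_equal(res$burden, res$tau_area_px / res$cell_count)
  # doubling the number of equal-size blobs doubles the burden
  slide2 <- gen_histology_image(seed = 5, n_cells = 12, n_tau = 6)
  res2 <- tau_burden(slide2$image)
  expect_equal(res2$cell_count, res$cell_count)
  expect_equal(res2$burden / res$burden, 2, tolerance = 0.02)
})

test_that("slide images round-trip through disk", {
  slide <- gen_histology_image(seed = 7, width = 96, height = 96,
                               n_cells = 3, n_tau = 1)
  path <- withr::local_tempfile(fileext = ".png")
  write_slide(slide$image, path)
  back <- read_slide(path)
  expect_equal(dim(back), dim(slide$image))
  expect_equal(back, slide$image, tolerance = 1e-8)
  expect_equal(tau_burden(back)$tau_area_px, slide$truth$tau_area_px)
})

test_that("generator colours are validated against the windows", {
  expect_error(
    gen_histology_image(seed = 1, width = 64, height = 64, n_cells = 1,
                        n_tau = 0, cell_hsb = c(20, 150, 120)),
    "window")
})
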