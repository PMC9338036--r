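test_that("pure pixels classify into the expected bands", {
  img <- image_from_hsv(h = c(0, 350, 220, 220, 120),
                        s = c(0.90, 0.80, 0.70, 0.05, 0.50),
                        v = c(0.60, 0.60, 0.60, 0.95, 0.50))
  cmap <- classify_pixels(img)
  # red, red (wraparound), blue, white, unclassified (green)
  expect_equal(as.integer(cmap), c(1L, 1L, 2L, 3L, 4L))
})

test_that("wraparound hue handling matches a brute-force interval check", {
  hues <- 0:359
  img <- image_from_hsv(hues, rep(0.5, 360), rep(0.5, 360))
  cmap <- classify_pixels(img)

  # independent oracle: recompute the quantised hue per pixel and test the
  # interval unions with plain logic
  rgb <- rbind(img[1, , 1], img[1, , 2], img[1, , 3])
  hq <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1, ] * 360
  oracle <- ifelse((hq >= 330 & hq <= 360) | hq <= 25, 1L,
                   ifelse(hq >= 170 & hq <= 260, 2L, 4L))
  expect_equal(as.integer(cmap), as.integer(oracle))
  # both red sub-intervals are actually exercised
  expect_gt(sum(hues >= 330 & cmap[1, ] == 1L), 0)
  expect_gt(sum(hues <= 25 & cmap[1, ] == 1L), 0)
})

test_that("class counts conserve the ROI pixel total", {
  m <- generate_micrograph(tiny_spec(fraction = 0.5, noise_sd = 8, seed = 30))
  cmap <- classify_pixels(m)
  a <- measure_areas(cmap)
  expect_equal(a$red_px + a$blue_px + a$white_px + a$unclassified_px, a$roi_px)
  expect_equal(a$roi_px, length(m$label_map))

  roi <- matrix(FALSE, nrow(m$label_map), ncol(m$label_map))
  roi[1:80, 1:80] <- TRUE
  a2 <- measure_areas(classify_pixels(m, roi = roi))
  expect_equal(a2$roi_px, 80 * 80)
  expect_error(classify_pixels(m, roi = roi & FALSE), "empty roi")
})

test_that("measure_areas counts exactly", {
  all_red <- make_class_map(matrix(1L, 10, 10))
  a <- measure_areas(all_red)
  expect_equal(a$red_px, 100)
  expect_equal(a$blue_px + a$white_px + a$unclassified_px, 0)

  checker <- make_class_map(matrix(rep(c(1L, 2L), length.out = 64), 8, 8))
  a2 <- measure_areas(checker)
  expect_equal(a2$red_px, 32)
  expect_equal(a2$blue_px, 32)

  m <- generate_micrograph(tiny_spec(fraction = 1, seed = 3))
  expect_equal(measure_areas(classify_pixels(m))$blue_px, 0)
})

test_that("compute_dcwl is the red fraction of the wall area", {
  rec <- compute_dcwl(measure_areas(make_class_map(
    matrix(c(rep(1L, 900), rep(2L, 300), rep(3L, 800)), 40, 50))))
  expect_equal(rec$dcwl, 0.75)

  expect_equal(compute_dcwl(measure_areas(make_class_map(matrix(2L, 40, 100))))$dcwl, 0)
  expect_equal(compute_dcwl(measure_areas(make_class_map(matrix(1L, 40, 100))))$dcwl, 1)
  expect_error(compute_dcwl(measure_areas(make_class_map(matrix(3L, 10, 10)))),
               "undefined DCWL")
})

test_that("noise-free segmentation recovers ground truth within 0.01", {
  for (fr in c(0.2, 0.5, 0.8)) {
    m <- generate_micrograph(tiny_spec(fraction = fr, noise_sd = 0, seed = 11))
    expect_lt(abs(dcwl_from_image(m)$dcwl - m$true_dcwl), 0.01)
  }
})

test_that("computed DCWL is monotone in the generator fraction at matched seeds", {
  for (sd_ in c(1, 2, 3)) {
    vals <- vapply(seq(0.1, 0.9, by = 0.2), function(fr) {
      dcwl_from_image(generate_micrograph(tiny_spec(fraction = fr, seed = sd_)))$dcwl
    }, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("white-balance normalisation is identity on neutral input and undoes a cast", {
  m <- generate_micrograph(tiny_spec(fraction = 0.6, seed = 21))
  patch <- list(rows = c(1, 12), cols = c(1, 12))  # background corner

  # a neutral grey patch leaves the image unchanged
  img <- m$image
  img[1:12, 1:12, ] <- 200L
  expect_identical(normalize_white_balance(img, patch), img)

  # a uniform 10% red cast is removed well enough that DCWL is preserved
  cast <- m$image
  cast[, , 1] <- as.integer(round(pmin(cast[, , 1] * 1.1, 255)))
  fixed <- normalize_white_balance(cast, patch)
  d0 <- dcwl_from_image(m)$dcwl
  expect_lt(abs(dcwl_from_image(fixed)$dcwl - d0), 0.01)

  black <- m$image
  black[1:12, 1:12, ] <- 0L
  expect_error(normalize_white_balance(black, patch), "black")
  sat <- m$image
  sat[1:12, 1:12, ] <- 255L
  expect_error(normalize_white_balance(sat, patch), "saturated")
})

test_that("threshold configs validate and round-trip through YAML, including the ImageJ scale", {
  dir <- withr::local_tempdir()
  th <- default_color_thresholds()
  p <- file.path(dir, "th.yaml")
  write_color_thresholds(th, p)
  expect_equal(read_color_thresholds(p), th)

  # same bands expressed on ImageJ's 0-255 scale
  ij <- list(scale = "imagej",
             red = list(hue = list(c(330, 360) / 360 * 255, c(0, 25) / 360 * 255),
                        sat = c(0.15, 1) * 255, val = c(0.15, 0.95) * 255),
             blue = list(hue = list(c(170, 260) / 360 * 255),
                         sat = c(0.15, 1) * 255, val = c(0.15, 0.95) * 255),
             white = list(hue = list(c(0, 360) / 360 * 255),
                          sat = c(0, 0.10) * 255, val = c(0.90, 1) * 255))
  pij <- file.path(dir, "ij.yaml")
  yaml::write_yaml(ij, pij)
  thij <- read_color_thresholds(pij)
  expect_equal(thij$red$hue[[1]], c(330, 360))
  expect_equal(thij$white$sat, c(0, 0.10))

  expect_error(color_thresholds(red = list(hue = list(c(30, 10)),
                                           sat = c(0, 1), val = c(0, 1)),
                                blue = th$blue, white = th$white),
               "malformed hue")
})

test_that("segment_images tabulates a directory of files", {
  dir <- withr::local_tempdir()
  specs <- lapply(c(0.2, 0.8), function(fr)
    tiny_spec(fraction = fr, seed = 4, width = 96, height = 96, scale = 0.15))
  truths <- numeric(2)
  for (i in 1:2) {
    m <- generate_micrograph(specs[[i]])
    truths[i] <- m$true_dcwl
    write_micrograph(m, dir, sprintf("img%d.png", i))
  }
  out_csv <- file.path(dir, "res.csv")
  tab <- segment_images(file.path(dir, c("img1.png", "img2.png")),
                        out_csv = out_csv)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dcwl, truths, tolerance = 0.01)
  expect_true(file.exists(out_csv))
  expect_equal(utils::read.csv(out_csv)$dcwl, tab$dcwl)
})
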