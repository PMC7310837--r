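test_that("parameter construction validates and scales with resolution", {
  p <- detection_params()
  expect_s3_class(p, "detection_params")
  expect_true(p$block_large > p$block_small && p$block_small >= 3)

  # doubling resolution doubles block sizes (kept odd) and quadruples areas
  p2 <- detection_params(resolution = 1)
  expect_equal(p2$block_large, 2 * p$block_large + 1)
  expect_equal(p2$min_pixels, 4 * p$min_pixels)
  expect_equal(p2$size_boundary, 4 * p$size_boundary)
  expect_equal(p2$min_feret, 2 * p$min_feret)
  # explicit values are never rescaled
  p3 <- detection_params(resolution = 1, block_large = 31, block_small = 9)
  expect_equal(p3$block_large, 31)

  expect_error(detection_params(block_large = 50), "odd")
  expect_error(detection_params(block_large = 9, block_small = 11), "block_large")
  expect_error(detection_params(c_small = -11), "-10")
  expect_error(detection_params(min_pixels = 400, size_boundary = 300),
               "size_boundary")
  expect_error(detection_params(resolution = 0), "resolution")
})

test_that("config files round-trip parameters with CLI-style overrides", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# detection settings", "mode = sem", "block_large = 41",
               "block_small = 9", "c_large = -5  # offset",
               "min_pixels = 30"), cfg)
  p <- read_config(cfg)
  expect_equal(p$mode, "sem")
  expect_equal(p$block_large, 41)
  expect_equal(p$c_large, -5)
  expect_equal(p$min_pixels, 30)
  p2 <- read_config(cfg, overrides = list(block_large = 61))
  expect_equal(p2$block_large, 61)
  writeLines("no_such_key = 1", cfg)
  expect_error(read_config(cfg), "unknown config key")
})

test_that("preprocessing handles channel isolation, inversion, and blur", {
  # fluor_red: green/blue content must not survive preprocessing
  img <- array(0, dim = c(20, 20, 3))
  img[5:8, 5:8, 2] <- 200  # green blob
  img[12:15, 12:15, 1] <- 200  # red blob
  p <- detection_params(mode = "fluor_red", blur_kernel = 1)
  g <- preprocess(img, p)
  expect_equal(max(g[5:8, 5:8]), 0)
  expect_gt(min(g[12:15, 12:15]), 200)

  # sem_dark inverts: uniform 40 -> 215
  img2 <- array(40, dim = c(10, 10, 3))
  p2 <- detection_params(mode = "sem_dark", blur_kernel = 1)
  expect_equal(unique(as.vector(preprocess(img2, p2))), 215)

  # blur_kernel = 1 is the identity on a luminance image
  set.seed(3)
  img3 <- array(runif(300, 0, 255), dim = c(10, 10, 3))
  p3 <- detection_params(blur_kernel = 1)
  expect_equal(preprocess(img3, p3), partseg:::luminance(img3))
  # blur preserves a constant image
  p4 <- detection_params(blur_kernel = 5)
  expect_true(all(abs(preprocess(img2, p4) - 40) < 1e-9))
})

test_that("adaptive threshold matches the brute-force neighborhood oracle", {
  # bright outlier is foreground at c = 0
  g <- matrix(50, 15, 15); g[8, 8] <- 200
  bw <- adaptive_threshold(g, 5, 0)
  expect_equal(bw[8, 8], 1L)
  # uniform image with c = -5: nothing can exceed mean + 5
  expect_equal(sum(adaptive_threshold(matrix(80, 10, 10), 5, -5)), 0)
  expect_error(adaptive_threshold(g, 4, 0), "odd")

  # per-pixel agreement with the direct-summation oracle on a random image
  set.seed(9)
  g4 <- matrix(runif(32 * 32, 0, 255), 32, 32)
  for (b in c(5, 9, 21)) {
    oracle_bw <- (g4 > oracle_local_mean(g4, b) - 2) * 1L
    expect_equal(unname(adaptive_threshold(g4, b, 2)), unname(oracle_bw))
  }

  # left-to-right ramp background + a patch at +60 on the dim side: the
  # adaptive threshold finds the patch, while no global threshold can
  # keep the patch foreground without misclassifying the ramp top
  ramp <- outer(rep(1, 64), seq(20, 120, length.out = 64))
  patch <- ramp
  patch[30:34, 5:9] <- patch[30:34, 5:9] + 60
  bw <- adaptive_threshold(patch, 21, 0)
  expect_true(all(bw[31:33, 6:8] == 1))
  patch_vals <- patch[30:34, 5:9]
  expect_true(max(patch_vals) < max(ramp)) # so a global cut cannot exist
  for (t in seq(0, 255, by = 1)) {
    fg_patch_full <- all(patch_vals > t)
    bg_ramp_clean <- all(ramp <= t)
    expect_false(fg_patch_full && bg_ramp_clean)
  }
})

test_that("otsu threshold maximizes between-class variance", {
  g <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  bw <- otsu_threshold(g)
  expect_equal(sum(bw), 50)
  expect_warning(bw0 <- otsu_threshold(matrix(7, 5, 5)), "constant")
  expect_equal(sum(bw0), 0)

  set.seed(21)
  g2 <- matrix(sample(c(60, 200), 400, replace = TRUE, prob = c(0.3, 0.7)), 20, 20)
  bw2 <- otsu_threshold(g2)
  expect_equal(attr(bw2, "threshold"), oracle_otsu(g2))
})

test_that("two passes split objects at the size boundary and filters apply", {
  g <- matrix(20, 100, 100)
  g[10:49, 10:49] <- 220   # 40x40 = 1600 px
  g[70:75, 70:75] <- 220   # 6x6 = 36 px
  p <- detection_params(size_boundary = 200, min_pixels = 20, min_feret = 0,
                        blur_kernel = 1)
  det <- detect_objects(g, p)
  expect_length(det, 2)
  passes <- sort(vapply(det, `[[`, "", "source_pass"))
  expect_equal(passes, c("large", "small"))
  areas <- sort(vapply(det, `[[`, 0, "area_px"))
  expect_equal(areas, c(36, 1600))

  # raising min_pixels filters the small square
  p2 <- detection_params(size_boundary = 200, min_pixels = 50, min_feret = 0,
                         blur_kernel = 1)
  expect_length(detect_objects(g, p2), 1)

  # all-dark image yields an empty list
  expect_length(detect_objects(matrix(10, 60, 60), detection_params()), 0)
})

test_that("pass-2 detections inside pass-1 objects are suppressed", {
  g <- matrix(20, 120, 120)
  g[20:69, 20:69] <- 220 # one large object claimed by pass 1
  p <- detection_params(size_boundary = 100, min_pixels = 20, min_feret = 0,
                        blur_kernel = 1)
  det <- detect_objects(g, p)
  expect_length(det, 1)
  expect_equal(det[[1]]$source_pass, "large")
})

test_that("no detection violates the min_pixels / min_feret filters", {
  for (s in 1:5) {
    sc <- generate_scene(scene_spec(seed = s, height = 200, width = 200,
                                    n_particles = 5, n_fibers = 2))
    p <- detection_params()
    det <- detect_particles(sc$image, p)
    expect_true(all(vapply(det, `[[`, 0, "area_px") >= p$min_pixels))
    expect_true(all(vapply(det, `[[`, 0, "feret_max_px") >= p$min_feret))
  }
})
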