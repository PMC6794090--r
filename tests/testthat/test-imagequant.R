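test_that("noiseless nuclei measure exactly and background subtracts", {
  img <- simulate_nucleus_image(3, intensities = c(100, 60, 25),
                                background_level = 20, noise_sd = 0,
                                seed = 2)
  m <- measure_nuclei(img$image, img$masks)
  expect_equal(m$net_intensity, c(80, 40, 5))
  expect_equal(unique(m$background_mean), 20)
  # negative nets are retained raw
  dim_img <- simulate_nucleus_image(1, intensities = 5,
                                    background_level = 20, noise_sd = 0,
                                    seed = 3)
  expect_lt(measure_nuclei(dim_img$image, dim_img$masks)$net_intensity, 0)
})

test_that("adding a constant to every pixel leaves net intensity unchanged", {
  img <- simulate_nucleus_image(4, intensities = c(30, 50, 70, 90),
                                background_level = 10, noise_sd = 2,
                                seed = 5)
  m0 <- measure_nuclei(img$image, img$masks)
  m1 <- measure_nuclei(img$image + 123.4, img$masks)
  expect_equal(m1$net_intensity, m0$net_intensity)
})

test_that("noisy implanted intensities are recovered within 3 SE", {
  truth <- rep(c(40, 80), 4)
  img <- simulate_nucleus_image(8, intensities = truth,
                                background_level = 20, noise_sd = 6,
                                seed = 8, dim = c(160, 160))
  m <- measure_nuclei(img$image, img$masks)
  for (k in seq_len(8)) {
    area <- sum(img$masks == k)
    expect_lt(abs(m$net_intensity[k] - (truth[k] - 20)),
              3 * 6 / sqrt(area) + 3 * 6 / sqrt(sum(img$masks == 0)))
  }
})

test_that("positive-cell counting matches construction", {
  img <- simulate_nucleus_image(16, intensities = 100,
                                background_level = 20, noise_sd = 1,
                                seed = 11, dim = c(200, 200))
  m <- measure_nuclei(img$image, img$masks, brain_id = "b1")
  cts <- count_positive_cells(m, threshold = 40)
  expect_equal(cts$n_cells, 16)
  expect_equal(cts$n_positive, 16)
  expect_equal(count_positive_cells(m, threshold = 1e6)$n_positive, 0)
  # mixed bright/dim brain counts exactly the bright ones
  mixed <- simulate_nucleus_image(10, intensities = rep(c(100, 22), 5),
                                  background_level = 20, noise_sd = 0,
                                  seed = 12, dim = c(200, 200))
  mm <- measure_nuclei(mixed$image, mixed$masks)
  expect_equal(count_positive_cells(mm, threshold = 40)$n_positive, 5)
  expect_error(count_positive_cells(mm, threshold = -1), "non-negative")
})

test_that("per-brain means average nuclei and ignore ordering", {
  m <- data.frame(brain_id = c("a", "a", "b"), cell_id = 1:3,
                  net_intensity = c(10, 30, 7))
  pb <- per_brain_mean(m)
  expect_equal(pb$mean_net_intensity[pb$brain_id == "a"], 20)
  expect_equal(pb$n_cells[pb$brain_id == "b"], 1)
  expect_equal(per_brain_mean(m[c(3, 1, 2), ]), pb)
})

test_that("background ROI validation catches overlap and emptiness", {
  img <- simulate_nucleus_image(2, intensities = 50, background_level = 10,
                                noise_sd = 0, seed = 7)
  bad <- img$masks > 0
  expect_error(measure_nuclei(img$image, img$masks, background_roi = bad),
               "overlaps")
  none <- matrix(FALSE, nrow(img$image), ncol(img$image))
  expect_error(measure_nuclei(img$image, img$masks, background_roi = none),
               "empty background")
  roi <- img$masks == 0 & row(img$masks) <= 20
  m <- measure_nuclei(img$image, img$masks, background_roi = roi)
  expect_equal(m$net_intensity, c(40, 40))
})
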