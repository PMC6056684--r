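test_that("ion images conserve total ion current at full-axis tolerance", {
  toy <- toy_ims(noise_sd = 0.4)
  d <- toy$dataset
  span <- max(d$mz_axis) - min(d$mz_axis)
  img <- ion_image(d, mean(range(d$mz_axis)), tolerance = span)
  tic <- rowSums(d$intensities)
  got <- img$values[cbind(d$coordinates[, "row"] + 1L,
                          d$coordinates[, "col"] + 1L)]
  expect_equal(got, tic)
  expect_true(all(img$values >= 0, na.rm = TRUE))
  expect_error(ion_image(d, 25000, tolerance = 10), "disjoint")
})

test_that("noise-free ion images localise to the planted region", {
  toy <- toy_ims(noise_sd = 0)
  img <- ion_image(toy$dataset, 5456, tolerance = 15)
  labs <- toy$phantom$labels
  base <- ion_image(toy$dataset, 15000, tolerance = 15) # no planted signal
  # signal pixels strictly exceed the shared baseline; elsewhere equal to it
  expect_true(all(img$values[labs == "lateral_wall"] >
                    base$values[labs == "lateral_wall"]))
  expect_equal(img$values[labs == "background"],
               base$values[labs == "background"])
  bg <- roi_stats(img, toy$phantom, "background")
  expect_equal(bg$mean, bg$max)  # flat baseline in background
})

test_that("mean_spectrum averages pixels and honours masks", {
  d <- ims_dataset(cbind(row = c(0, 0), col = c(0, 1)),
                   mz_axis = c(100, 200, 300),
                   intensities = rbind(c(1, 2, 3), 3 * c(1, 2, 3)))
  expect_equal(mean_spectrum(d), 2 * c(1, 2, 3))
  expect_equal(mean_spectrum(d, c(TRUE, FALSE)), c(1, 2, 3))
  expect_error(mean_spectrum(d, c(FALSE, FALSE)), "no pixels")
  toy <- toy_ims(noise_sd = 0)
  mask <- toy$phantom$labels == "lateral_wall"
  ms <- mean_spectrum(toy$dataset, mask)
  i_mz <- which(toy$dataset$mz_axis == 5456)
  planted_height <- toy$signal$base_intensity * 4 # ouabain multiplier
  expect_lt(abs((ms[i_mz] - 1) - planted_height) / planted_height, 0.01)
})

test_that("peak picking finds planted peaks and thins close neighbours", {
  mz <- default_mz_axis(step = 2)
  centers <- c(4878, 5456, 11353)
  sp <- 5 + rowSums(vapply(centers, function(c_) {
    100 * exp(-(mz - c_)^2 / (2 * 9))
  }, numeric(length(mz))))
  pk <- pick_peaks(sp, mz, snr_threshold = 5, min_separation_da = 50)
  expect_equal(nrow(pk), 3)
  expect_true(all(vapply(centers,
                         function(c_) min(abs(pk$mz - c_)) <= 2,
                         logical(1))))
  # flat spectrum yields nothing
  expect_equal(nrow(pick_peaks(rep(3, 1000), seq_len(1000) + 2000)), 0)
  # two peaks 4 Da apart under a 10 Da separation: keep the taller one
  sp2 <- 60 * exp(-(mz - 5456)^2 / 2) + 30 * exp(-(mz - 5460)^2 / 2)
  pk2 <- pick_peaks(sp2, mz, snr_threshold = 5, min_separation_da = 10)
  near <- pk2[abs(pk2$mz - 5458) < 10, ]
  expect_equal(nrow(near), 1)
  expect_lt(abs(near$mz - 5456), 3)
})

test_that("peak picking recovers planted centres across simulation seeds", {
  mz_axis <- default_mz_axis(step = 5)
  for (seed in 1:5) {
    ph <- make_phantom(c(20, 20), seed = seed)
    sigs <- list(
      planted_signal(5456, 6, "lateral_wall", 30, c(ouabain = 4)),
      planted_signal(11353, 8, "auditory_nerve", 30, c(ouabain = 4))
    )
    d <- simulate_ims(ph, sigs, "ouabain", mz_axis, noise_sd = 0.3,
                      baseline = 1, seed = seed)
    pk <- pick_peaks(mean_spectrum(d), mz_axis, snr_threshold = 5,
                     min_separation_da = 50, min_rel_intensity = 0.01)
    for (c_ in c(5456, 11353)) {
      expect_lte(min(abs(pk$mz - c_)), 5)
    }
  }
})

test_that("roi_stats summarises regions and rejects absent ones", {
  toy <- toy_ims(noise_sd = 0)
  img <- ion_image(toy$dataset, 5456, tolerance = 15)
  uniform <- img
  uniform$values[] <- 7
  st <- roi_stats(uniform, toy$phantom, "other_cochlea")
  expect_equal(st$mean, 7)
  expect_equal(st$max, 7)
  expect_error(roi_stats(img, toy$phantom, "organ_of_corti"), "no pixels")
  lw <- roi_stats(img, toy$phantom, "lateral_wall")
  expect_lte(lw$mean, lw$max)
  expect_gt(lw$n_pixels, 0)
})

test_that("injury monotonicity ranks severity against density", {
  up <- injury_monotonicity(c(control = 1, "106dB" = 2, "112dB" = 3,
                              ouabain = 4))
  expect_equal(up$spearman_rho, 1)
  expect_true(up$is_strictly_increasing)
  down <- injury_monotonicity(c(a = 4, b = 3, c = 2, d = 1))
  expect_equal(down$spearman_rho, -1)
  expect_false(down$is_strictly_increasing)
  expect_error(injury_monotonicity(c(a = 1, b = 2)), "at least 3")
})

test_that("cross-run signal matching unifies known alias pairs only", {
  expect_true(match_signals(5456, 5458))
  expect_true(match_signals(11353, 11356))
  expect_true(match_signals(6199, 6197))
  expect_false(match_signals(5456, 6199))
  expect_false(match_signals(5456, 5667))
  expect_error(match_signals(-5, 10), "positive")
  expect_s3_class(mz_signal(5456, aliases = 5458), "MzSignal")
  expect_error(mz_signal(5456, aliases = 6199), "not within tolerance")
})

test_that("overlay composites are max-normalised per channel", {
  toy <- toy_ims(noise_sd = 0)
  img <- ion_image(toy$dataset, 5456, tolerance = 15)
  comp <- overlay(list(img), "red")
  expect_equal(dim(comp), c(dim(img$values), 3))
  norm <- img$values / max(img$values)
  expect_equal(comp[, , 1], norm)
  expect_true(all(comp[, , 2:3] == 0))
  # six distinctly coloured images keep six distinct channels populated
  imgs <- rep(list(img), 6)
  cols <- c("red", "green", "blue", "yellow", "purple", "white")
  comp6 <- overlay(imgs, cols)
  expect_true(all(comp6 >= 0 & comp6 <= 1))
  zero <- img; zero$values[] <- 0
  expect_true(all(overlay(list(zero), "red") == 0))
  bad <- img; bad$values <- bad$values[-1, ]
  expect_error(overlay(list(img, bad), c("red", "blue")), "share one grid")
})
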