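test_that("phantom label maps contain every region and are reproducible", {
  ph <- make_phantom(c(64, 64), pixel_pitch = 50, seed = 1)
  expect_setequal(unique(as.vector(ph$labels)),
                  c("background", "lateral_wall", "auditory_nerve",
                    "reissner_membrane", "other_cochlea"))
  ph2 <- make_phantom(c(64, 64), pixel_pitch = 50, seed = 1)
  expect_identical(ph$labels, ph2$labels)
  # minimum viable grid still carries all regions
  small <- make_phantom(c(16, 16), seed = 5)
  expect_true(all(c("lateral_wall", "auditory_nerve", "reissner_membrane")
                  %in% small$labels))
  expect_error(make_phantom(c(8, 8)), "too small")
})

test_that("noise-free IMS simulation plants exact region-scaled peaks", {
  ph <- make_phantom(c(20, 20), seed = 3)
  mz_axis <- default_mz_axis(step = 4)
  mult <- c(control = 1, "112dB" = 2)
  sig <- planted_signal(5456, 6, "lateral_wall", 10, mult)
  ctrl <- simulate_ims(ph, list(sig), "control", mz_axis, noise_sd = 0,
                       baseline = 1, seed = 1)
  hi <- simulate_ims(ph, list(sig), "112dB", mz_axis, noise_sd = 0,
                     baseline = 1, seed = 1)
  i_mz <- which(mz_axis == 5456)
  labs <- ph$labels[cbind(ctrl$coordinates[, "row"] + 1L,
                          ctrl$coordinates[, "col"] + 1L)]
  lw <- labs == "lateral_wall"
  bg <- labs == "background"
  # lateral-wall pixels at the centre are exactly baseline + height, and the
  # 112 dB peak height is exactly twice the control height
  expect_equal(unique(ctrl$intensities[lw, i_mz]), 1 + 10)
  expect_equal(unique(hi$intensities[lw, i_mz] - 1),
               2 * unique(ctrl$intensities[lw, i_mz] - 1))
  expect_equal(unique(ctrl$intensities[bg, i_mz]), 1)
  expect_error(
    simulate_ims(ph, list(planted_signal(25000, 5, "lateral_wall", 1,
                                         mult)),
                 "control", mz_axis),
    "outside")
})

test_that("IMS simulation is byte-identical for a fixed seed and monotone in severity", {
  ph <- make_phantom(c(20, 20), seed = 3)
  mz_axis <- default_mz_axis(step = 4)
  mult <- c(control = 1, "106dB" = 2, "112dB" = 3, ouabain = 4)
  sig <- planted_signal(5456, 6, "lateral_wall", 10, mult)
  a <- simulate_ims(ph, list(sig), "ouabain", mz_axis, noise_sd = 0.4,
                    baseline = 1, seed = 7)
  b <- simulate_ims(ph, list(sig), "ouabain", mz_axis, noise_sd = 0.4,
                    baseline = 1, seed = 7)
  expect_identical(a$intensities, b$intensities)
  # noise-free ROI means strictly increase with the severity ranking
  means <- vapply(names(mult), function(cond) {
    d <- simulate_ims(ph, list(sig), cond, mz_axis, noise_sd = 0,
                      baseline = 1, seed = 1)
    img <- ion_image(d, 5456, tolerance = 15)
    roi_stats(img, ph, "lateral_wall")$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  mono <- injury_monotonicity(means, names(mult))
  expect_equal(mono$spearman_rho, 1)
  expect_true(mono$is_strictly_increasing)
})

test_that("simulated proteomes are mass self-consistent", {
  cat_ <- simulate_proteome(100, mw_range = c(3000, 13000),
                            chain_fraction = 0, seed = 7)
  expect_length(cat_, 100)
  for (rec in cat_) {
    expect_lt(abs(rec$mw_da - average_mass(rec$sequence)), 0.01)
    expect_length(rec$chains, 0)
    expect_true(rec$mw_da >= 3000 && rec$mw_da <= 13000)
  }
  withchains <- simulate_proteome(50, chain_fraction = 1, seed = 7)
  for (rec in withchains) {
    expect_length(rec$chains, 1)
    ch <- rec$chains[[1]]
    expect_lt(ch$chain_mass_da, rec$mw_da)
    expect_equal(ch$chain_mass_da,
                 average_mass(substr(rec$sequence, ch$start, ch$end)))
  }
  expect_error(simulate_proteome(10, mw_range = c(5000, 5000)), "empty")
  expect_error(simulate_proteome(10, mw_range = c(100, 5000)), "within")
})

test_that("expression simulation calibrates under the null and separates planted effects", {
  # null: planted and unplanted p-value distributions indistinguishable
  null0 <- simulate_expression(1000, n_per_group = 3, n_de = 100,
                               effect_size = 0, seed = 11)
  de0 <- test_all_genes(null0$matrix, null0$labels)
  planted <- de0$gene %in% null0$ground_truth$de_gene_ids
  ks <- suppressWarnings(ks.test(de0$p[planted], de0$p[!planted]))
  expect_gt(ks$p.value, 0.01)
  # null type-I calibration within 3 binomial SE
  null_only <- simulate_expression(1000, n_per_group = 3, n_de = 0, seed = 2)
  frac <- mean(test_all_genes(null_only$matrix, null_only$labels)$significant)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  # 3-sigma planted effects: majority detected at p < 0.05
  eff <- simulate_expression(1000, n_per_group = 3, n_de = 100,
                             effect_size = 3, seed = 11)
  de <- test_all_genes(eff$matrix, eff$labels)
  sens <- mean(eff$ground_truth$de_gene_ids %in% de$gene[de$significant])
  expect_gt(sens, 0.5)
  expect_error(simulate_expression(100, n_per_group = 1), "t-test undefined")
})

test_that("spectral-count simulation is Poisson with exact zeros", {
  cat_ <- simulate_proteome(100, seed = 1)
  ab <- matrix(10, nrow = 100, ncol = 2,
               dimnames = list(vapply(cat_, `[[`, character(1), "accession"),
                               c("control", "ouabain")))
  ab[1, ] <- c(0, 5)
  rep_ <- simulate_msms(cat_, ab, seed = 4)
  rep2 <- simulate_msms(cat_, ab, seed = 4)
  expect_identical(rep_, rep2)
  expect_identical(rep_$control[1], 0L)
  # mean of unit-mean-10 counts within 3 SE of 10
  counts <- c(rep_$control[-1], rep_$ouabain[-1])
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / length(counts)))
  ab[2, 1] <- -1
  expect_error(simulate_msms(cat_, ab, seed = 1), "negative")
})
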