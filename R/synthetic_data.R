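# Synthetic ground-truth generators. Every input the workflow consumes can be
# simulated here with a fixed seed: a phantom cochlear section (label map),
# imaging-MS datacubes with region-localised, injury-severity-scaled peaks,
# a proteome catalogue with self-consistent masses, two-group expression
# matrices with planted effects, and Poisson spectral-count tables.

REGION_CODES <- c("background", "lateral_wall", "auditory_nerve",
                  "reissner_membrane", "other_cochlea")

#' Severity ordering of the study conditions
#'
#' Control, then 106 dB and 112 dB noise exposure, then ouabain — the
#' low-to-high injury ranking used for monotonicity checks.
#' @export
CONDITION_ORDER <- c("control", "106dB", "112dB", "ouabain")

# Evaluate expr with a local RNG stream; the caller's global RNG state is
# untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be one integer")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Phantom cochlear section label map
#'
#' Approximates a mid-modiolar section as concentric annular bands on a
#' square grid: a central auditory-nerve disk, a surrounding cochlear
#' annulus whose outer band is the lateral wall, a thin radial spoke for
#' Reissner's membrane, and background outside. Exact geometry is cosmetic;
#' only region membership matters downstream.
#'
#' @param grid_shape Integer `(rows, cols)`, each >= 16.
#' @param pixel_pitch Micrometers per pixel (metadata only).
#' @param seed Integer seed (orients the membrane spoke).
#' @return A `PhantomLabelMap`: `labels` (character matrix of region codes),
#'   `grid_shape`, `pixel_pitch`.
#' @export
make_phantom <- function(grid_shape = c(64, 64), pixel_pitch = 50, seed = 1) {
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  if (rows < 16L || cols < 16L) {
    stop("grid too small: need at least 16x16, got ", rows, "x", cols)
  }
  with_seed(seed, {
    cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
    rmax <- 0.48 * min(rows, cols)
    ri <- matrix(rep(seq_len(rows), cols), nrow = rows)
    ci <- matrix(rep(seq_len(cols), each = rows), nrow = rows)
    r <- sqrt((ri - cr)^2 + (ci - cc)^2) / rmax
    labels <- matrix("background", rows, cols)
    labels[r < 0.75] <- "other_cochlea"
    labels[r >= 0.62 & r < 0.75] <- "lateral_wall"
    labels[r < 0.22] <- "auditory_nerve"
    # Reissner's membrane: one-pixel-wide radial spoke at a random angle,
    # marked by walking outward so it is never empty.
    theta <- stats::runif(1, 0, 2 * pi)
    for (rad in seq(0.26, 0.58, by = 0.25 / rmax)) {
      pr <- as.integer(round(cr + rad * rmax * sin(theta)))
      pc <- as.integer(round(cc + rad * rmax * cos(theta)))
      if (pr >= 1 && pr <= rows && pc >= 1 && pc <= cols) {
        labels[pr, pc] <- "reissner_membrane"
      }
    }
    structure(
      list(labels = labels, grid_shape = c(rows, cols),
           pixel_pitch = pixel_pitch),
      class = "PhantomLabelMap"
    )
  })
}

#' @export
print.PhantomLabelMap <- function(x, ...) {
  cat(sprintf("PhantomLabelMap: %dx%d px, pitch %g um\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch))
  print(table(x$labels))
  invisible(x)
}

#' A planted m/z signal for the IMS simulator
#'
#' @param center_mz Peak centre, Da.
#' @param peak_width Gaussian sigma, Da.
#' @param region Region code the signal localises to.
#' @param base_intensity Peak height in the reference condition, a.u.
#' @param severity_multipliers Named non-negative multipliers, one per
#'   condition (e.g. `c(control = 1, "106dB" = 2, ...)`).
#' @return A `PlantedSignal`.
#' @export
planted_signal <- function(center_mz, peak_width, region, base_intensity,
                           severity_multipliers) {
  stopifnot(region %in% REGION_CODES, base_intensity >= 0)
  if (any(severity_multipliers < 0)) stop("multipliers must be >= 0")
  structure(
    list(center_mz = center_mz, peak_width = peak_width, region = region,
         base_intensity = base_intensity,
         severity_multipliers = severity_multipliers),
    class = "PlantedSignal"
  )
}

#' Simulate an imaging-MS datacube over a phantom
#'
#' Each pixel's spectrum is `baseline` plus, for every planted signal whose
#' region contains the pixel, a Gaussian peak scaled by the signal's
#' severity multiplier for `condition`, plus Gaussian noise, clipped at 0.
#'
#' @param phantom A `PhantomLabelMap`.
#' @param signals List of `PlantedSignal`s.
#' @param condition Condition label; must have a multiplier in every signal.
#' @param mz_axis Acquisition axis, Da.
#' @param noise_sd Additive Gaussian noise SD (>= 0), a.u.
#' @param baseline Constant baseline intensity, a.u.
#' @param seed Integer seed.
#' @return An `IMSDataset` covering every phantom pixel.
#' @export
simulate_ims <- function(phantom, signals, condition,
                         mz_axis = default_mz_axis(), noise_sd = 0,
                         baseline = 0, seed = 1) {
  stopifnot(inherits(phantom, "PhantomLabelMap"), noise_sd >= 0)
  for (s in signals) {
    if (s$center_mz < min(mz_axis) || s$center_mz > max(mz_axis)) {
      stop("signal centre ", s$center_mz, " outside the m/z axis")
    }
    if (!condition %in% names(s$severity_multipliers)) {
      stop("no severity multiplier for condition '", condition, "'")
    }
  }
  rows <- phantom$grid_shape[1]; cols <- phantom$grid_shape[2]
  coords <- cbind(
    row = rep(seq_len(rows) - 1L, times = cols),
    col = rep(seq_len(cols) - 1L, each = rows)
  )
  npx <- nrow(coords); nmz <- length(mz_axis)
  with_seed(seed, {
    intens <- matrix(baseline, nrow = npx, ncol = nmz)
    labs <- phantom$labels[cbind(coords[, "row"] + 1L, coords[, "col"] + 1L)]
    for (s in signals) {
      shape <- s$base_intensity * s$severity_multipliers[[condition]] *
        exp(-(mz_axis - s$center_mz)^2 / (2 * s$peak_width^2))
      member <- labs == s$region
      if (any(member)) {
        intens[member, ] <- intens[member, , drop = FALSE] +
          rep(shape, each = sum(member))
      }
    }
    if (noise_sd > 0) {
      intens <- intens + matrix(stats::rnorm(npx * nmz, sd = noise_sd),
                                nrow = npx)
    }
    intens[intens < 0] <- 0
    ims_dataset(coords, mz_axis, intens, pixel_pitch = phantom$pixel_pitch,
                condition = condition)
  })
}

#' Simulate a proteome catalogue
#'
#' Random amino-acid sequences (uniform over the 20 standard residues) with
#' lengths tuned so computed average masses fall in `mw_range`; the stored
#' molecular weight is always recomputed from the sequence, so records are
#' self-consistent by construction. A fraction of records carry one random
#' chain feature (a proper subsequence) with its computed chain mass.
#'
#' @param n_records Number of records (>= 1).
#' @param mw_range Length-2 numeric, Da; must lie inside (500, 5e6).
#' @param chain_fraction Fraction of records given a chain feature.
#' @param seed Integer seed.
#' @return List of `ProteomeRecord`s.
#' @export
simulate_proteome <- function(n_records, mw_range = c(3000, 13000),
                              chain_fraction = 0, seed = 1) {
  stopifnot(n_records >= 1L, chain_fraction >= 0, chain_fraction <= 1)
  if (length(mw_range) != 2L || mw_range[1] >= mw_range[2]) {
    stop("empty molecular-weight range")
  }
  if (mw_range[1] <= 500 || mw_range[2] >= 5e6) {
    stop("mw_range must lie within (500, 5e6) Da")
  }
  aa <- names(.AA_AVERAGE)
  mean_res <- mean(.AA_AVERAGE)
  with_seed(seed, {
    n_chain <- round(chain_fraction * n_records)
    chain_recs <- if (n_chain > 0) sample.int(n_records, n_chain) else integer(0)
    lapply(seq_len(n_records), function(i) {
      target <- stats::runif(1, mw_range[1], mw_range[2])
      len <- max(4L, as.integer(round((target - .WATER_AVERAGE) / mean_res)))
      seq_ <- paste(sample(aa, len, replace = TRUE), collapse = "")
      # nudge into range with glycines / truncation
      while (average_mass(seq_) > mw_range[2]) {
        seq_ <- substr(seq_, 1, nchar(seq_) - 1L)
      }
      while (average_mass(seq_) < mw_range[1]) {
        seq_ <- paste0(seq_, "G")
      }
      rec <- proteome_record(
        accession = sprintf("SYN%04d", i),
        name = sprintf("Synthetic protein %d", i),
        sequence = seq_
      )
      if (i %in% chain_recs) {
        L <- nchar(seq_)
        start <- sample(2:max(2L, L %/% 2L), 1)
        end <- sample(start:(L - 1L), 1)
        rec <- add_chain(rec, sprintf("Synthetic chain %d", i), start, end)
      }
      rec
    })
  })
}

#' Simulate a normalized two-group expression matrix with planted effects
#'
#' Null genes are Gaussian with the same mean in both groups; `n_de` planted
#' genes are shifted by `effect_size` standard deviations in the treatment
#' group, emulating an RMA-normalized microarray comparison of injured vs
#' control auditory nerve.
#'
#' @param n_genes Number of genes/probes.
#' @param n_per_group Samples per group (>= 2).
#' @param n_de Number of planted differentially expressed genes.
#' @param effect_size Mean shift in SD units.
#' @param seed Integer seed.
#' @param mu,sigma Null distribution parameters (log2-scale expression).
#' @param de_gene_ids Optional explicit ids to plant (defaults to a random
#'   subset of size `n_de`).
#' @return List: `matrix` (genes x samples), `labels` (character vector,
#'   "control"/"treatment"), `ground_truth` (planted ids, effect, seed).
#' @export
simulate_expression <- function(n_genes, n_per_group = 3, n_de = 0,
                                effect_size = 0, seed = 1, mu = 8, sigma = 1,
                                de_gene_ids = NULL) {
  if (n_per_group < 2L) stop("t-test undefined with fewer than 2 per group")
  stopifnot(n_de <= n_genes)
  gene_ids <- sprintf("probe_%05d", seq_len(n_genes))
  with_seed(seed, {
    if (is.null(de_gene_ids)) {
      de_gene_ids <- if (n_de > 0) sample(gene_ids, n_de) else character(0)
    } else {
      stopifnot(all(de_gene_ids %in% gene_ids))
    }
    n_samp <- 2L * n_per_group
    m <- matrix(stats::rnorm(n_genes * n_samp, mean = mu, sd = sigma),
                nrow = n_genes,
                dimnames = list(gene_ids, c(
                  sprintf("control_%d", seq_len(n_per_group)),
                  sprintf("treatment_%d", seq_len(n_per_group))
                )))
    labels <- rep(c("control", "treatment"), each = n_per_group)
    trt <- labels == "treatment"
    m[de_gene_ids, trt] <- m[de_gene_ids, trt] + effect_size * sigma
    list(
      matrix = m, labels = labels,
      ground_truth = list(de_gene_ids = sort(de_gene_ids),
                          effect_size = effect_size, seed = seed)
    )
  })
}

#' Simulate an LC-MS/MS spectral-count report
#'
#' Counts are Poisson with the supplied per-protein, per-condition means;
#' a mean of zero yields an exact zero count.
#'
#' @param proteome_subset List of `ProteomeRecord`s to report on.
#' @param abundance_map Numeric matrix of Poisson means, proteins x
#'   conditions, rownames = accessions (all >= 0).
#' @param conditions Condition names (columns of `abundance_map`).
#' @param seed Integer seed.
#' @return An `MsmsReport` data frame: accession, protein, mw_kda, one count
#'   column per condition.
#' @export
simulate_msms <- function(proteome_subset, abundance_map,
                          conditions = colnames(abundance_map), seed = 1) {
  abundance_map <- as.matrix(abundance_map)
  if (any(abundance_map < 0)) stop("negative abundance is not allowed")
  accs <- vapply(proteome_subset, function(r) r$accession, character(1))
  stopifnot(all(accs %in% rownames(abundance_map)),
            length(conditions) == ncol(abundance_map))
  colnames(abundance_map) <- conditions
  with_seed(seed, {
    counts <- matrix(0L, nrow = length(accs), ncol = length(conditions),
                     dimnames = list(accs, conditions))
    for (j in seq_along(conditions)) {
      mu <- abundance_map[accs, j]
      pos <- mu > 0
      counts[pos, j] <- stats::rpois(sum(pos), mu[pos])
    }
    msms_report(
      accession = accs,
      protein = vapply(proteome_subset, function(r) r$name, character(1)),
      mw_kda = round(vapply(proteome_subset, function(r) r$mw_da,
                            numeric(1)) / 1000, 1),
      counts = counts
    )
  })
}

#' Simulate a coherent multi-omic bundle with known ground truth
#'
#' Builds every pipeline input from one seed: a phantom section; four IMS
#' datacubes (control, 106 dB, 112 dB, ouabain) carrying two planted
#' injury-monotone signals (multipliers 1,2,3,4) — one in the lateral wall
#' near m/z 5456 and one in the auditory nerve near m/z 11353; a proteome
#' catalogue in which exactly two records ("true" proteins) carry mature
#' chains whose masses sit at the planted m/z values while all other
#' reported proteins lie outside every +/- 1 kDa window; noise- and
#' ouabain-model expression matrices in which the true proteins' probes are
#' planted as differentially expressed; a probe map; a spectral-count report
#' and peptide evidence favouring the true proteins.
#'
#' @param seed Integer seed driving every generator.
#' @param grid_shape Phantom size in pixels.
#' @param n_genes Genes per expression matrix.
#' @param n_per_group Samples per group.
#' @param noise_sd IMS additive noise SD.
#' @return List with components `phantom`, `ims` (one `IMSDataset` per
#'   condition), `catalogue`, `expr_noise`, `expr_ouabain`, `probe_map`,
#'   `msms`, `peptide_evidence`, `ground_truth`.
#' @export
simulate_bundle <- function(seed = 1, grid_shape = c(32, 32), n_genes = 1000,
                            n_per_group = 3, noise_sd = 0.5) {
  target_mz <- c(5456, 11353)
  mult <- c(control = 1, "106dB" = 2, "112dB" = 3, ouabain = 4)
  phantom <- make_phantom(grid_shape, pixel_pitch = 50, seed = seed)
  signals <- list(
    planted_signal(target_mz[1], peak_width = 6, region = "lateral_wall",
                   base_intensity = 40, severity_multipliers = mult),
    planted_signal(target_mz[2], peak_width = 8, region = "auditory_nerve",
                   base_intensity = 30, severity_multipliers = mult)
  )
  mz_axis <- default_mz_axis(step = 4)
  ims <- lapply(CONDITION_ORDER, function(cond) {
    simulate_ims(phantom, signals, cond, mz_axis, noise_sd = noise_sd,
                 baseline = 2, seed = seed + match(cond, CONDITION_ORDER))
  })
  names(ims) <- CONDITION_ORDER

  catalogue <- simulate_proteome(80, mw_range = c(3000, 18000),
                                 chain_fraction = 0.3, seed = seed + 11)
  # two ground-truth proteins: precursor = 20-residue propeptide + mature
  # chain tuned to the planted m/z
  catalogue <- with_seed(seed + 12, {
    aa <- names(.AA_AVERAGE)
    for (k in seq_along(target_mz)) {
      len <- as.integer(round((target_mz[k] - .WATER_AVERAGE) /
                                mean(.AA_AVERAGE)))
      mature <- paste(sample(aa, len, replace = TRUE), collapse = "")
      while (average_mass(mature) > target_mz[k] + 25) {
        mature <- substr(mature, 1, nchar(mature) - 1L)
      }
      while (average_mass(mature) < target_mz[k] - 25) {
        mature <- paste0(mature, "G")
      }
      pro <- paste(sample(aa, 20, replace = TRUE), collapse = "")
      seq_ <- paste0(pro, mature)
      rec <- proteome_record(sprintf("TRUE%04d", k),
                             sprintf("Planted injury protein %d", k), seq_)
      rec <- add_chain(rec, sprintf("Planted mature chain %d", k),
                       21L, nchar(seq_))
      catalogue[[length(catalogue) + 1L]] <- rec
    }
    catalogue
  })
  true_accs <- c("TRUE0001", "TRUE0002")

  # probe map: one probe per catalogue record, named after the accession
  accs <- vapply(catalogue, function(r) r$accession, character(1))
  gene_ids <- sprintf("probe_%05d", seq_len(n_genes))
  probe_map <- data.frame(
    probe_id = gene_ids[seq_along(accs)],
    accession = accs,
    symbol = tolower(accs),
    stringsAsFactors = FALSE
  )
  true_probes <- probe_map$probe_id[match(true_accs, probe_map$accession)]

  # plant the true probes (strongly) plus background DE genes in both models
  plant <- function(extra_seed, n_extra) {
    extra <- setdiff(gene_ids, true_probes)
    with_seed(seed + extra_seed, sample(extra, n_extra))
  }
  de_noise_ids <- c(true_probes, plant(21, 30))
  de_ouab_ids <- c(true_probes, plant(22, 80))
  expr_noise <- simulate_expression(n_genes, n_per_group,
                                    n_de = length(de_noise_ids),
                                    effect_size = 5, seed = seed + 31,
                                    de_gene_ids = de_noise_ids)
  expr_ouabain <- simulate_expression(n_genes, n_per_group,
                                      n_de = length(de_ouab_ids),
                                      effect_size = 5, seed = seed + 32,
                                      de_gene_ids = de_ouab_ids)

  # MS/MS report: the true proteins plus decoys whose masses (full-length
  # and chains) lie outside every target window
  win_lo <- target_mz - 1100; win_hi <- target_mz + 1100
  outside <- vapply(catalogue, function(r) {
    masses <- c(r$mw_da,
                vapply(r$chains, function(c_) c_$chain_mass_da, numeric(1)))
    all(vapply(masses, function(m) all(m < win_lo | m > win_hi), logical(1)))
  }, logical(1))
  decoys <- with_seed(seed + 41,
                      sample(which(outside), min(20, sum(outside))))
  subset <- c(catalogue[decoys], catalogue[match(true_accs, accs)])
  sub_accs <- vapply(subset, function(r) r$accession, character(1))
  abundance <- with_seed(seed + 42, {
    ab <- matrix(stats::runif(length(sub_accs) * 2, 1, 8),
                 ncol = 2, dimnames = list(sub_accs, c("control", "ouabain")))
    ab[true_accs, ] <- rep(c(1, 10), each = 2)
    ab
  })
  msms <- simulate_msms(subset, abundance, c("control", "ouabain"),
                        seed = seed + 43)
  peptide_evidence <- data.frame(
    accession = sub_accs,
    n_peptides = with_seed(seed + 44,
                           pmax(2L, stats::rpois(length(sub_accs), 4))),
    stringsAsFactors = FALSE
  )

  list(
    phantom = phantom, ims = ims, catalogue = catalogue,
    expr_noise = expr_noise, expr_ouabain = expr_ouabain,
    probe_map = probe_map, msms = msms,
    peptide_evidence = peptide_evidence,
    ground_truth = list(
      true_accessions = true_accs, target_mz = target_mz,
      true_probes = true_probes, severity_multipliers = mult, seed = seed
    )
  )
}
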