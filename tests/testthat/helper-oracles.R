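# Independent oracles and small fixture builders used across the suite.

# Brute-force linear scan over a catalogue: the reference answer for
# query_candidates, written without reusing its code path.
brute_force_pool <- function(catalogue, low, high, include_chains = TRUE) {
  hits <- character(0)
  for (rec in catalogue) {
    if (rec$mw_da >= low && rec$mw_da <= high) {
      hits <- c(hits, paste0(rec$accession, ":protein"))
    }
    if (include_chains) {
      for (ch in rec$chains) {
        if (ch$chain_mass_da >= low && ch$chain_mass_da <= high) {
          hits <- c(hits, paste0(rec$accession, ":chain:", ch$start, "-",
                                 ch$end))
        }
      }
    }
  }
  sort(hits)
}

pool_keys <- function(pool) {
  cand <- pool$candidates
  keys <- ifelse(cand$entity == "protein",
                 paste0(cand$accession, ":protein"),
                 paste0(cand$accession, ":chain:", cand$chain_start, "-",
                        cand$chain_end))
  sort(keys)
}

# Exhaustive balanced two-group permutation p-value for |t| (equal group
# sizes), including the observed assignment.
exact_perm_p <- function(x, y) {
  v <- c(x, y)
  n <- length(v)
  combos <- utils::combn(n, length(x))
  tobs <- abs(student_t_test(x, y)$t)
  tperm <- apply(combos, 2, function(ix) {
    abs(student_t_test(v[ix], v[-ix])$t)
  })
  mean(tperm >= tobs - 1e-12)
}

# A tiny deterministic catalogue with known masses for window tests.
toy_catalogue <- function() {
  recs <- list(
    proteome_record("ACC1", "toy one", sequence = strrep("G", 80)),
    proteome_record("ACC2", "toy two", mw_da = 5456),
    proteome_record("ACC3", "toy three", mw_da = 11353),
    proteome_record("ACC4", "toy four", mw_da = 30000)
  )
  recs[[4]] <- add_chain(recs[[4]], "toy four chain", 1, 10,
                         chain_mass_da = 4950)
  recs
}

# Noise-free single-signal dataset over a small phantom.
toy_ims <- function(condition = "ouabain", multiplier = 4, noise_sd = 0,
                    seed = 3) {
  phantom <- make_phantom(c(20, 20), pixel_pitch = 50, seed = seed)
  sig <- planted_signal(5456, peak_width = 6, region = "lateral_wall",
                        base_intensity = 10,
                        severity_multipliers = c(control = 1,
                                                 ouabain = multiplier))
  list(
    phantom = phantom,
    signal = sig,
    dataset = simulate_ims(phantom, list(sig), condition,
                           mz_axis = default_mz_axis(step = 4),
                           noise_sd = noise_sd, baseline = 1, seed = seed)
  )
}
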