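# LC-MS/MS evidence integration: protein-level spectral-count reports,
# condition set analysis, semi-quantitative abundance ranking, and the final
# synthesis — intersecting identified proteins (through their mature-chain
# masses) with the m/z candidate windows and gating on differential mRNA
# expression.

#' Construct a protein-level spectral-count report
#'
#' @param accession Unique accessions.
#' @param protein Protein names.
#' @param mw_kda Full-length molecular weight, kDa (report precision).
#' @param counts Integer matrix, proteins x conditions, with condition
#'   column names; all counts >= 0.
#' @return An `MsmsReport` data frame with one count column per condition
#'   and the condition names in `attr(, "conditions")`.
#' @export
msms_report <- function(accession, protein, mw_kda, counts) {
  counts <- as.matrix(counts)
  if (anyDuplicated(accession)) stop("accessions must be unique per row")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spectral counts must be non-negative integers")
  }
  out <- data.frame(accession = accession, protein = protein,
                    mw_kda = mw_kda, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(counts))) out[[colnames(counts)[j]]] <- counts[, j]
  attr(out, "conditions") <- colnames(counts)
  class(out) <- c("MsmsReport", "data.frame")
  out
}

#' Apply the minimum-peptides identification filter
#'
#' Protein identifications are conventionally accepted only with at least
#' two distinct peptides. `evidence` may give one row per observed peptide
#' (columns `accession`, `peptide`) or pre-counted rows (`accession`,
#' `n_peptides`).
#'
#' @param evidence Peptide evidence data frame.
#' @param min_peptides Minimum distinct peptides (default 2).
#' @return Character vector of accepted accessions.
#' @export
filter_min_peptides <- function(evidence, min_peptides = 2) {
  if ("n_peptides" %in% names(evidence)) {
    counts <- stats::setNames(evidence$n_peptides, evidence$accession)
  } else if ("peptide" %in% names(evidence)) {
    counts <- vapply(split(evidence$peptide, evidence$accession),
                     function(p) length(unique(p)), numeric(1))
  } else {
    stop("evidence needs a 'peptide' or 'n_peptides' column")
  }
  sort(names(counts)[counts >= min_peptides])
}

#' Condition set analysis of an MS/MS report
#'
#' Partitions the report's proteins into those unique to condition `a`
#' (count > 0 in `a`, exactly 0 in `b`), unique to `b`, detected in both,
#' and absent from both.
#'
#' @param report An `MsmsReport`.
#' @param a,b Condition (count column) names.
#' @return List of accession vectors `unique_to_a`, `unique_to_b`, `shared`,
#'   `absent`.
#' @export
condition_sets <- function(report, a, b) {
  if (!a %in% names(report) || !b %in% names(report)) {
    stop("unknown condition name: ", paste(setdiff(c(a, b), names(report)),
                                           collapse = ", "))
  }
  ca <- report[[a]]; cb <- report[[b]]
  list(
    unique_to_a = report$accession[ca > 0 & cb == 0],
    unique_to_b = report$accession[cb > 0 & ca == 0],
    shared = report$accession[ca > 0 & cb > 0],
    absent = report$accession[ca == 0 & cb == 0]
  )
}

#' Rank proteins by spectral counts
#'
#' Total spectral counts as a semi-quantitative abundance proxy: descending
#' by the chosen condition's count, ties broken by total count (descending)
#' then accession (ascending).
#'
#' @param report An `MsmsReport`.
#' @param condition Count column to rank by.
#' @param restrict_to Optional accession subset (e.g. condition-unique
#'   proteins).
#' @return The report rows in rank order.
#' @export
rank_by_spectral_counts <- function(report, condition, restrict_to = NULL) {
  if (!condition %in% names(report)) stop("unknown condition: ", condition)
  conds <- attr(report, "conditions")
  rows <- if (is.null(restrict_to)) report else
    report[report$accession %in% restrict_to, , drop = FALSE]
  total <- rowSums(as.matrix(rows[, conds, drop = FALSE]))
  ord <- order(-rows[[condition]], -total, rows$accession)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match identified proteins to m/z signals through mass windows
#'
#' Emits one synthesis row for every (signal, entity) pair whose mass lies
#' in the signal's molecular-weight window. By default only annotated chain
#' features are matched: protein-report full-length weights are printed in
#' kDa at a precision coarser than the window half-width, whereas chain
#' masses are known to the dalton. One entity may match several signals.
#'
#' @param identified Data frame of identified proteins: `accession`, `name`,
#'   and (for full-length matching) `mw_da`.
#' @param chain_features Data frame of chains: `accession`, `chain_name`,
#'   `start`, `end`, `chain_mass_da`; only chains of identified accessions
#'   are considered.
#' @param signals Numeric vector of m/z values (or list of `MzSignal`s).
#' @param delta Window half-width, Da.
#' @param match_full_length Also match full-length `mw_da` values.
#' @return A `SynthesisRow` data frame: signal, accession, name, chain
#'   coordinates, mass_da.
#' @export
match_ids_to_signals <- function(identified, chain_features = NULL,
                                 signals, delta = 1000,
                                 match_full_length = FALSE) {
  mzs <- vapply(signals, function(s) {
    if (inherits(s, "MzSignal")) s$canonical_mz else as.numeric(s)
  }, numeric(1))
  entities <- data.frame(
    accession = character(0), name = character(0),
    chain_start = integer(0), chain_end = integer(0), mass_da = numeric(0),
    stringsAsFactors = FALSE
  )
  if (match_full_length && "mw_da" %in% names(identified)) {
    entities <- rbind(entities, data.frame(
      accession = identified$accession, name = identified$name,
      chain_start = NA_integer_, chain_end = NA_integer_,
      mass_da = identified$mw_da, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(chain_features) && nrow(chain_features) > 0) {
    ch <- chain_features[chain_features$accession %in% identified$accession, ,
                         drop = FALSE]
    if (nrow(ch) > 0) {
      entities <- rbind(entities, data.frame(
        accession = ch$accession, name = ch$chain_name,
        chain_start = ch$start, chain_end = ch$end,
        mass_da = ch$chain_mass_da, stringsAsFactors = FALSE
      ))
    }
  }
  rows <- list()
  for (mz in mzs) {
    w <- mw_window(mz, delta)
    hit <- entities$mass_da >= w$low & entities$mass_da <= w$high
    if (any(hit)) {
      h <- entities[hit, , drop = FALSE]
      h <- h[order(abs(h$mass_da - mz), h$accession), , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(signal = mz, h)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    cbind(signal = numeric(0), entities)
  rownames(out) <- NULL
  class(out) <- c("SynthesisRow", "data.frame")
  out
}

#' Final identification calls
#'
#' A synthesis row becomes a final (signal -> protein) call when at least
#' one probe mapped to its accession is significant (`p < alpha`) in either
#' injury model's differential-expression results. Rows without any probe
#' mapping are left uncalled and reported.
#'
#' @param synthesis_rows Output of [match_ids_to_signals()].
#' @param de_results A `DEResult` data frame or a list of them (one per
#'   injury model).
#' @param probe_map Data frame `probe_id`, `accession`.
#' @param alpha Significance gate (default 0.05).
#' @return List: `calls` (called rows, with `probe_set` and `p_value`
#'   columns), `uncalled_no_mapping` (accessions with no probe mapping),
#'   `rows` (all rows with the call flag).
#' @export
final_calls <- function(synthesis_rows, de_results, probe_map, alpha = 0.05) {
  if (inherits(de_results, "data.frame")) de_results <- list(de_results)
  rows <- synthesis_rows
  rows$probe_set <- NA_character_
  rows$p_value <- NA_real_
  rows$called <- FALSE
  probes_of <- split(probe_map$probe_id, probe_map$accession)
  for (i in seq_len(nrow(rows))) {
    pr <- probes_of[[rows$accession[i]]]
    if (is.null(pr)) next
    best_p <- Inf; best_probe <- NA_character_
    for (de in de_results) {
      sub <- de[de$gene %in% pr, , drop = FALSE]
      if (nrow(sub) > 0 && min(sub$p) < best_p) {
        best_p <- min(sub$p)
        best_probe <- sub$gene[which.min(sub$p)]
      }
    }
    if (is.finite(best_p)) {
      rows$probe_set[i] <- best_probe
      rows$p_value[i] <- best_p
      rows$called[i] <- best_p < alpha
    }
  }
  no_map <- unique(rows$accession[!rows$accession %in% names(probes_of)])
  list(calls = rows[rows$called, , drop = FALSE],
       uncalled_no_mapping = no_map, rows = rows)
}
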