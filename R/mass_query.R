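# Molecular-weight window query against a proteome catalogue: the in-package
# equivalent of a TagIdent search. Intact proteins observed by linear-mode
# MALDI-TOF in the 2-20 kDa range are taken as singly charged, so an m/z
# signal is queried directly as a molecular weight with a symmetric window.

# Average (isotope-abundance-weighted) residue masses, Da. ExPASy convention:
# residue mass = amino-acid mass - one water; protein mass = sum + water.
.AA_AVERAGE <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Monoisotopic residue masses, Da.
.AA_MONO <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

.WATER_AVERAGE <- 18.0153
.WATER_MONO <- 18.010565

#' Protein mass from amino-acid sequence
#'
#' Computes the uncharged molecular mass of a polypeptide as the sum of its
#' residue masses plus one water. Average masses are the default, matching
#' what linear-mode MALDI-TOF measures for intact proteins; monoisotopic
#' masses are available for high-resolution work.
#'
#' @param sequence Character scalar of one-letter codes for the 20 standard
#'   amino acids.
#' @param monoisotopic Logical; use monoisotopic residue masses instead of
#'   average masses.
#' @return Mass in daltons.
#' @examples
#' average_mass("GG")
#' @export
average_mass <- function(sequence, monoisotopic = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop("empty sequence has no defined protein mass")
  }
  tab <- if (monoisotopic) .AA_MONO else .AA_AVERAGE
  water <- if (monoisotopic) .WATER_MONO else .WATER_AVERAGE
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(residues), names(tab))
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  sum(tab[residues]) + water
}

#' Mass of an annotated chain (mature subsequence)
#'
#' Many secreted or processed proteins are observed not as the full-length
#' precursor but as an annotated chain (e.g. the thrombin light chain,
#' residues 325-360 of prothrombin). The chain mass is the mass of the
#' subsequence alone, with its own terminal water.
#'
#' @param record A `ProteomeRecord` (see [proteome_record()]) carrying a
#'   sequence, or a plain sequence string.
#' @param start,end 1-based inclusive residue positions.
#' @param monoisotopic Passed to [average_mass()].
#' @return Chain mass in daltons.
#' @export
chain_mass <- function(record, start, end, monoisotopic = FALSE) {
  sequence <- if (inherits(record, "ProteomeRecord")) record$sequence else record
  if (is.null(sequence) || is.na(sequence) || !nzchar(sequence)) {
    stop("record carries no sequence; chain mass undefined")
  }
  n <- nchar(sequence)
  if (!(start >= 1L && start <= end && end <= n)) {
    stop("chain bounds [", start, ", ", end, "] violate 1 <= start <= end <= ",
         n)
  }
  average_mass(substr(sequence, start, end), monoisotopic = monoisotopic)
}

#' Molecular-weight search window around an m/z signal
#'
#' For a singly charged MALDI ion the m/z value is read directly as a
#' molecular weight and the search window is `mz - delta` to `mz + delta`.
#' The default half-width of 1 kDa absorbs mass error and moderate
#' post-translational modifications. No proton-mass correction is applied:
#' the window is centred on the printed m/z itself.
#'
#' @param mz Observed m/z, Da.
#' @param delta Window half-width, Da (default 1000).
#' @return An object of class `MwWindow` with fields `center`, `delta`,
#'   `low`, `high`.
#' @examples
#' mw_window(4878)   # 3878 - 5878
#' @export
mw_window <- function(mz, delta = 1000) {
  stopifnot(is.numeric(mz), length(mz) == 1L, is.numeric(delta))
  if (!(mz > delta && delta >= 0)) {
    stop("require mz > delta >= 0; got mz=", mz, ", delta=", delta)
  }
  structure(
    list(center = mz, delta = delta, low = mz - delta, high = mz + delta),
    class = "MwWindow"
  )
}

#' @export
print.MwWindow <- function(x, ...) {
  cat(sprintf("MwWindow: %g +/- %g Da  [%g, %g]\n",
              x$center, x$delta, x$low, x$high))
  invisible(x)
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Maximum relative mass change admitted by a window
#'
#' The window half-width expressed as an integer percentage of the signal,
#' i.e. the largest relative mass shift a candidate may carry and still fall
#' in the window. Rounding is half away from zero.
#'
#' @param mz Signal m/z, Da.
#' @param delta Window half-width, Da.
#' @return Integer percent.
#' @examples
#' max_percent_change(11353, 1000)  # 9
#' @export
max_percent_change <- function(mz, delta) {
  stopifnot(mz > 0, delta >= 0)
  as.integer(round_half_away(100 * delta / mz))
}

#' Construct a proteome catalogue record
#'
#' @param accession Identifier (e.g. UniProt accession).
#' @param name Protein name.
#' @param sequence Optional amino-acid sequence; when given and `mw_da` is
#'   missing, the stored mass is computed from it.
#' @param mw_da Average molecular mass, Da.
#' @param taxon Optional taxon identifier.
#' @return A `ProteomeRecord`.
#' @export
proteome_record <- function(accession, name = accession, sequence = NA_character_,
                            mw_da = NULL, taxon = NA_character_) {
  if (is.null(mw_da)) {
    if (is.na(sequence)) stop("need sequence or mw_da")
    mw_da <- average_mass(sequence)
  }
  stopifnot(mw_da > 0)
  if (!is.na(sequence) && nzchar(sequence) &&
      abs(mw_da - average_mass(sequence)) >= 0.5) {
    stop("stored mw_da disagrees with sequence mass by >= 0.5 Da for ",
         accession)
  }
  structure(
    list(accession = accession, name = name, sequence = sequence,
         mw_da = mw_da, taxon = taxon, chains = list()),
    class = "ProteomeRecord"
  )
}

#' Attach a chain feature to a catalogue record
#'
#' @param record A `ProteomeRecord`.
#' @param chain_name Name of the mature chain.
#' @param start,end 1-based inclusive residue positions.
#' @param chain_mass_da Optional; computed from the sequence when absent.
#' @return The record with the chain appended.
#' @export
add_chain <- function(record, chain_name, start, end, chain_mass_da = NULL) {
  stopifnot(inherits(record, "ProteomeRecord"))
  if (is.null(chain_mass_da)) {
    chain_mass_da <- chain_mass(record, start, end)
  }
  if (chain_mass_da > record$mw_da + 1e-9) {
    stop("chain mass exceeds parent full-length mass for ", record$accession)
  }
  record$chains[[length(record$chains) + 1L]] <- list(
    parent = record$accession, chain_name = chain_name,
    start = as.integer(start), end = as.integer(end),
    chain_mass_da = chain_mass_da
  )
  record
}

# Flatten a catalogue (list of ProteomeRecord) to one row per queryable
# entity: full-length records plus chain features.
.catalogue_entities <- function(catalogue, include_chains = TRUE) {
  stopifnot(length(catalogue) > 0L)
  rows <- lapply(catalogue, function(rec) {
    out <- data.frame(
      accession = rec$accession, name = rec$name, entity = "protein",
      chain_name = NA_character_, chain_start = NA_integer_,
      chain_end = NA_integer_, mass_da = rec$mw_da,
      stringsAsFactors = FALSE
    )
    if (include_chains && length(rec$chains) > 0L) {
      ch <- do.call(rbind, lapply(rec$chains, function(c_) {
        data.frame(
          accession = rec$accession, name = rec$name, entity = "chain",
          chain_name = c_$chain_name, chain_start = c_$start,
          chain_end = c_$end, mass_da = c_$chain_mass_da,
          stringsAsFactors = FALSE
        )
      }))
      out <- rbind(out, ch)
    }
    out
  })
  do.call(rbind, rows)
}

#' Enumerate catalogue entries inside a molecular-weight window
#'
#' Returns every full-length record (and, optionally, every annotated chain)
#' whose mass lies in the closed window, ordered by distance from the window
#' centre, ties broken by accession.
#'
#' @param catalogue List of `ProteomeRecord`s.
#' @param window An `MwWindow`.
#' @param include_chains Also match chain features by their chain mass.
#' @return A `CandidatePool`: list with `window` and a data frame
#'   `candidates` (accession, name, entity, chain coordinates, mass_da).
#' @export
query_candidates <- function(catalogue, window, include_chains = TRUE) {
  stopifnot(inherits(window, "MwWindow"))
  ents <- .catalogue_entities(catalogue, include_chains = include_chains)
  hit <- ents$mass_da >= window$low & ents$mass_da <= window$high
  hits <- ents[hit, , drop = FALSE]
  ord <- order(abs(hits$mass_da - window$center), hits$accession)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(window = window, candidates = hits), class = "CandidatePool")
}

#' @export
print.CandidatePool <- function(x, ...) {
  cat(sprintf("CandidatePool: %d entr%s in [%g, %g] Da\n",
              nrow(x$candidates), if (nrow(x$candidates) == 1) "y" else "ies",
              x$window$low, x$window$high))
  if (nrow(x$candidates) > 0) print(utils::head(x$candidates, 10))
  invisible(x)
}
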