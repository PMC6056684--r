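# File formats. Imaging data moves as imzML (continuous mode: one shared m/z
# axis in the .ibd binary, one intensity block per pixel) or as a plain-text
# container (a single TSV with metadata comment lines). Proteome catalogues
# move as FASTA plus a chain-feature TSV; expression matrices, probe maps,
# reports and pools as TSV.

.new_uuid <- function() {
  b <- as.integer(sample(0:255, 16, replace = TRUE))
  b[7] <- bitwOr(bitwAnd(b[7], 15L), 64L)   # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 63L), 128L)  # variant
  h <- sprintf("%02x", b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

#' Write an imaging-MS dataset to imzML (continuous mode)
#'
#' Writes `<path>.imzML` (XML index) and `<path>.ibd` (binary: 16-byte UUID,
#' then the shared 64-bit m/z axis once, then one 32-bit intensity block per
#' pixel). Pixel positions are written 1-based per the imzML convention
#' (x = column + 1, y = row + 1).
#'
#' @param dataset An `IMSDataset`.
#' @param path Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "IMSDataset"))
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")
  uuid <- .new_uuid()
  con <- file(ibd_path, "wb")
  writeBin(as.raw(strtoi(substring(gsub("-", "", uuid),
                                   seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  writeBin(as.numeric(dataset$mz_axis), con, size = 8, endian = "little")
  npx <- nrow(dataset$intensities)
  for (i in seq_len(npx)) {
    writeBin(as.numeric(dataset$intensities[i, ]), con, size = 4,
             endian = "little")
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  nmz <- length(dataset$mz_axis)
  mz_offset <- 16
  mz_len_bytes <- nmz * 8
  int_offsets <- mz_offset + mz_len_bytes + (seq_len(npx) - 1) * nmz * 4
  xs <- dataset$coordinates[, "col"] + 1L
  ys <- dataset$coordinates[, "row"] + 1L

  spectra <- vapply(seq_len(npx), function(i) {
    paste0(
      '<spectrum id="spectrum=', i, '" index="', i - 1L,
      '" defaultArrayLength="', nmz, '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      xs[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      ys[i], '"/>',
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      nmz, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      mz_offset, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      mz_len_bytes, '"/>',
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      nmz, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      sprintf("%.0f", int_offsets[i]), '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      nmz * 4, '"/>',
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>"
    )
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{',
    uuid, '}"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="',
    toupper(md5), '"/>',
    '<userParam name="condition" value="', dataset$condition, '"/>',
    '<userParam name="pixel_pitch_um" value="', dataset$pixel_pitch, '"/>',
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<softwareList count="1"><software id="imstx" version="',
    as.character(utils::packageVersion("imstx")), '"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="',
    max(xs), '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="',
    max(ys), '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="',
    dataset$pixel_pitch, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="',
    dataset$pixel_pitch, '"/>',
    "</scanSettings></scanSettingsList>",
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    "</instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="imstx">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    "</processingMethod></dataProcessing></dataProcessingList>",
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', npx, '">',
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>\n"
  )
  writeLines(xml, xml_path, sep = "")
  invisible(c(imzml = xml_path, ibd = ibd_path))
}

#' Read a continuous-mode imzML file
#'
#' @param path Path to the `.imzML` file (the `.ibd` sibling is located by
#'   name).
#' @return An `IMSDataset`.
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing binary sibling: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mode <- xml2::xml_find_first(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']")
  if (inherits(mode, "xml_missing")) {
    stop("only continuous-mode imzML is supported")
  }
  getp <- function(node, acc) {
    xml2::xml_attr(xml2::xml_find_first(
      node, paste0(".//cvParam[@accession='", acc, "']")), "value")
  }
  cond <- xml2::xml_attr(xml2::xml_find_first(
    doc, "//fileContent/userParam[@name='condition']"), "value")
  pitch <- xml2::xml_attr(xml2::xml_find_first(
    doc, "//fileContent/userParam[@name='pixel_pitch_um']"), "value")
  if (is.na(pitch)) {
    pitch <- getp(doc, "IMS:1000046")
  }
  mz_bits <- if (!inherits(xml2::xml_find_first(
    doc, "//referenceableParamGroup[@id='mzArray']/cvParam[@accession='MS:1000523']"),
    "xml_missing")) 8L else 4L
  int_bits <- if (!inherits(xml2::xml_find_first(
    doc, "//referenceableParamGroup[@id='intensityArray']/cvParam[@accession='MS:1000523']"),
    "xml_missing")) 8L else 4L

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  npx <- length(spectra)
  if (npx == 0L) stop("no spectra in ", path)
  xs <- ys <- integer(npx)
  mz_off <- int_off <- mz_n <- int_n <- numeric(npx)
  for (i in seq_len(npx)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(getp(sp, "IMS:1000050"))
    ys[i] <- as.integer(getp(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      off <- as.numeric(getp(arr, "IMS:1000102"))
      n <- as.numeric(getp(arr, "IMS:1000103"))
      if (identical(ref, "mzArray")) {
        mz_off[i] <- off; mz_n[i] <- n
      } else {
        int_off[i] <- off; int_n[i] <- n
      }
    }
  }
  con <- file(ibd_path, "rb")
  on.exit(close(con))
  seek(con, mz_off[1])
  mz_axis <- readBin(con, numeric(), n = mz_n[1], size = mz_bits,
                     endian = "little")
  intens <- matrix(0, nrow = npx, ncol = mz_n[1])
  for (i in seq_len(npx)) {
    seek(con, int_off[i])
    intens[i, ] <- readBin(con, numeric(), n = int_n[i], size = int_bits,
                           endian = "little")
  }
  coords <- cbind(row = ys - 1L, col = xs - 1L)
  ims_dataset(coords, mz_axis, intens,
              pixel_pitch = if (is.na(pitch)) 50 else as.numeric(pitch),
              condition = if (is.na(cond)) "unspecified" else cond)
}

#' Write an imaging-MS dataset to the plain-text container
#'
#' A single TSV: `#key=value` metadata comment lines, then a header
#' `row  col  <mz1> <mz2> ...` and one line per pixel.
#'
#' @param dataset An `IMSDataset`.
#' @param path Output TSV path.
#' @export
write_ims_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "IMSDataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#condition=", dataset$condition),
    paste0("#pixel_pitch_um=", dataset$pixel_pitch)
  ), con)
  tab <- cbind(dataset$coordinates, dataset$intensities)
  colnames(tab) <- c("row", "col", format(dataset$mz_axis, trim = TRUE,
                                          scientific = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the plain-text imaging container
#'
#' @param path TSV path written by [write_ims_tsv()].
#' @return An `IMSDataset`.
#' @export
read_ims_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  getmeta <- function(key, default) {
    m <- meta[startsWith(meta, paste0("#", key, "="))]
    if (length(m) == 0) default else sub(paste0("^#", key, "="), "", m[1])
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", check.names = FALSE)
  mz_axis <- as.numeric(colnames(tab)[-(1:2)])
  ims_dataset(as.matrix(tab[, 1:2]), mz_axis, as.matrix(tab[, -(1:2)]),
              pixel_pitch = as.numeric(getmeta("pixel_pitch_um", "50")),
              condition = getmeta("condition", "unspecified"))
}

#' Write a proteome catalogue to FASTA plus a feature TSV
#'
#' Sequenced records go to `<path>.fasta` with `sp|ACC|NAME`-style headers;
#' all records and their chain features go to `<path>_features.tsv`
#' (accession, name, mw_da, chain_start, chain_end, chain_mass_da, taxon),
#' one row per full-length record and one per chain.
#'
#' @param catalogue List of `ProteomeRecord`s.
#' @param path Output path stem.
#' @export
write_catalogue <- function(catalogue, path) {
  seqs <- Filter(function(r) !is.na(r$sequence) && nzchar(r$sequence),
                 catalogue)
  if (length(seqs) > 0) {
    ss <- Biostrings::AAStringSet(vapply(seqs, `[[`, character(1), "sequence"))
    names(ss) <- vapply(seqs, function(r) {
      paste0("sp|", r$accession, "|", gsub("\\s+", "_", r$name))
    }, character(1))
    Biostrings::writeXStringSet(ss, paste0(path, ".fasta"))
  }
  rows <- lapply(catalogue, function(r) {
    base <- data.frame(accession = r$accession, name = r$name,
                       mw_da = r$mw_da, chain_start = NA_integer_,
                       chain_end = NA_integer_, chain_mass_da = NA_real_,
                       chain_name = NA_character_,
                       taxon = r$taxon, stringsAsFactors = FALSE)
    if (length(r$chains) > 0) {
      ch <- do.call(rbind, lapply(r$chains, function(c_) {
        data.frame(accession = r$accession, name = r$name, mw_da = r$mw_da,
                   chain_start = c_$start, chain_end = c_$end,
                   chain_mass_da = c_$chain_mass_da,
                   chain_name = c_$chain_name, taxon = r$taxon,
                   stringsAsFactors = FALSE)
      }))
      base <- rbind(base, ch)
    }
    base
  })
  utils::write.table(do.call(rbind, rows), paste0(path, "_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accession from a FASTA header: second pipe-delimited field when present,
# else the first whitespace-delimited token.
.parse_accession <- function(header) {
  tok <- strsplit(header, "\\s+")[[1]][1]
  parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2) parts[2] else parts[1]
}

#' Read a proteome catalogue from FASTA and/or a feature TSV
#'
#' @param fasta Optional FASTA path; sequences attach to feature rows by
#'   accession. With no feature table, records are built from the sequences
#'   alone.
#' @param features Optional feature TSV as written by [write_catalogue()].
#' @return List of `ProteomeRecord`s.
#' @export
read_catalogue <- function(fasta = NULL, features = NULL) {
  if (is.null(fasta) && is.null(features)) stop("need fasta and/or features")
  seqs <- character(0)
  if (!is.null(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss),
                            vapply(names(ss), .parse_accession, character(1)))
  }
  if (is.null(features)) {
    return(lapply(names(seqs), function(acc) {
      proteome_record(acc, name = acc, sequence = unname(seqs[acc]))
    }))
  }
  tab <- utils::read.table(features, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  recs <- list()
  for (acc in unique(tab$accession)) {
    sub <- tab[tab$accession == acc, , drop = FALSE]
    main <- sub[is.na(sub$chain_start), , drop = FALSE]
    info <- if (nrow(main) > 0) main[1, ] else sub[1, ]
    seq_ <- if (acc %in% names(seqs)) unname(seqs[acc]) else NA_character_
    rec <- proteome_record(acc, name = info$name, sequence = seq_,
                           mw_da = info$mw_da,
                           taxon = if ("taxon" %in% names(info))
                             as.character(info$taxon) else NA_character_)
    ch <- sub[!is.na(sub$chain_start), , drop = FALSE]
    for (i in seq_len(nrow(ch))) {
      rec <- add_chain(rec,
                       chain_name = if (!is.na(ch$chain_name[i]))
                         ch$chain_name[i] else paste0(acc, "_chain"),
                       start = ch$chain_start[i], end = ch$chain_end[i],
                       chain_mass_da = ch$chain_mass_da[i])
    }
    recs[[length(recs) + 1L]] <- rec
  }
  recs
}

#' Write an expression matrix with group labels
#'
#' The matrix goes to `path`; the two-column sample/group sidecar to
#' `<path stem>_groups.tsv`.
#'
#' @param matrix_ Genes x samples matrix with dimnames.
#' @param labels Group label per sample.
#' @param path Output TSV path.
#' @export
write_expression <- function(matrix_, labels, path) {
  utils::write.table(
    data.frame(gene = rownames(matrix_), matrix_, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(matrix_), group = labels),
    sub("\\.tsv$", "_groups.tsv", path),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and its group sidecar
#'
#' @param path TSV written by [write_expression()].
#' @return List: `matrix`, `labels`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  groups <- utils::read.table(sub("\\.tsv$", "_groups.tsv", path), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  list(matrix = m, labels = groups$group[match(colnames(m), groups$sample)])
}

#' Read a spectral-count report TSV
#'
#' Expects columns `protein`, `accession`, `mw_kda`, then one count column
#' per condition (the bundled reference table layout).
#'
#' @param path TSV path.
#' @return An `MsmsReport`.
#' @export
read_msms_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  conds <- setdiff(names(tab), c("protein", "accession", "mw_kda"))
  msms_report(tab$accession, tab$protein, tab$mw_kda,
              as.matrix(tab[, conds, drop = FALSE]))
}

#' Export an ion image as a TSV grid (and optionally PNG)
#'
#' @param image An `IonImage`.
#' @param path Output TSV path; with `png = TRUE` a max-normalised grayscale
#'   `<path>.png` is also written (requires the `png` package).
#' @param png Also write a PNG.
#' @export
write_ion_image <- function(image, path, png = FALSE) {
  utils::write.table(image$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (png) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required for PNG export")
    }
    v <- image$values
    v[is.na(v)] <- 0
    if (max(v) > 0) v <- v / max(v)
    png::writePNG(v, paste0(path, ".png"))
  }
  invisible(path)
}
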