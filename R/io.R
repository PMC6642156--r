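# All tabular artifacts are tab-separated text with a header row; numeric
# cells are printed with 17 significant digits so write -> read round-trips
# to full double precision.

write_tsv_precise <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]])) df2[[j]] <- sprintf("%.17g", df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# parses character columns expected to be numeric; errors name the column
# and 1-based data line of the first offending cell
as_numeric_checked <- function(x, col, path) {
  if (is.numeric(x)) return(x)  # already parsed at full precision
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x))
  if (length(bad))
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "', line ", bad[1] + 1L, " of ", path)
  y
}

#' Read / write channel-to-sample design files
#'
#' Tab-separated with columns `set_id`, `channel`, `sample`, `subtype`.
#'
#' @param design A `sample_design` data frame.
#' @param path File path.
#' @return `read_design` returns the validated `sample_design`.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  write_tsv_precise(as.data.frame(design), path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- read_tsv_checked(path)
  d$channel <- as.character(d$channel)
  validate_design(d)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read / write protein quantification tables
#'
#' Tab-separated: a `protein_id` column followed by one numeric column per
#' channel. Duplicate protein ids and non-numeric cells are reported with
#' their line number.
#'
#' @param table A [protein_quant_table()].
#' @param path File path of the table.
#' @param design Optional `sample_design` (or path to one) attached on
#'   read.
#' @return `read_quant_table` returns a [protein_quant_table()].
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "protein_quant_table"))
  df <- data.frame(protein_id = rownames(table$sn),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$sn, optional = TRUE))
  write_tsv_precise(df, path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path, design = NULL) {
  df <- read_tsv_checked(path)
  if (!"protein_id" %in% names(df))
    stop("read_quant_table: missing 'protein_id' column in ", path)
  if (ncol(df) < 2L)
    stop("read_quant_table: no channel columns in ", path)
  dup <- which(duplicated(df$protein_id))
  if (length(dup))
    stop("read_quant_table: duplicate protein id '",
         df$protein_id[dup[1]], "' at line ", dup[1] + 1L, " of ", path)
  sn <- vapply(names(df)[-1],
               function(cn) as_numeric_checked(df[[cn]], cn, path),
               numeric(nrow(df)))
  sn <- matrix(sn, nrow = nrow(df),
               dimnames = list(df$protein_id, names(df)[-1]))
  if (is.character(design)) design <- read_design(design)
  protein_quant_table(sn, design)
}

#' Read / write merged fold-change matrices
#'
#' The matrix file holds linear fold changes (`protein_id` column plus one
#' column per sample); the sidecar design file holds columns `sample`,
#' `subtype`, `set_id`.
#'
#' @param matrix A [fold_change_matrix()].
#' @param path Matrix file path.
#' @param design_path Sidecar design file path.
#' @return `read_fold_change_matrix` returns a [fold_change_matrix()].
#' @export
write_fold_change_matrix <- function(matrix, path, design_path) {
  stopifnot(inherits(matrix, "fold_change_matrix"))
  df <- data.frame(protein_id = rownames(matrix$fc),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(matrix$fc, optional = TRUE))
  write_tsv_precise(df, path)
  sid <- if (is.null(matrix$set_id))
    rep(NA_character_, ncol(matrix$fc)) else unname(matrix$set_id)
  write_tsv_precise(
    data.frame(sample = colnames(matrix$fc),
               subtype = unname(matrix$subtype), set_id = sid,
               stringsAsFactors = FALSE),
    design_path)
  invisible(path)
}

#' @rdname write_fold_change_matrix
#' @export
read_fold_change_matrix <- function(path, design_path) {
  df <- read_tsv_checked(path)
  if (!"protein_id" %in% names(df))
    stop("read_fold_change_matrix: missing 'protein_id' column in ", path)
  dup <- which(duplicated(df$protein_id))
  if (length(dup))
    stop("read_fold_change_matrix: duplicate protein id '",
         df$protein_id[dup[1]], "' at line ", dup[1] + 1L)
  fc <- vapply(names(df)[-1],
               function(cn) as_numeric_checked(df[[cn]], cn, path),
               numeric(nrow(df)))
  fc <- matrix(fc, nrow = nrow(df),
               dimnames = list(df$protein_id, names(df)[-1]))
  sd <- read_tsv_checked(design_path)
  fold_change_matrix(fc,
                     stats::setNames(sd$subtype, sd$sample),
                     stats::setNames(as.character(sd$set_id), sd$sample))
}

#' Read / write expression matrices
#'
#' Tab-separated: `feature_id` column plus one numeric column per sample.
#' The sidecar subtype file has columns `sample`, `subtype`.
#'
#' @param matrix An [expression_matrix()].
#' @param path Matrix file path.
#' @param subtype_path Sidecar sample-to-subtype file.
#' @param platform Platform tag for `read_expression_matrix`.
#' @param probe_map_path Optional probe-to-gene map file (columns `probe`,
#'   `gene`).
#' @return `read_expression_matrix` returns an [expression_matrix()].
#' @export
write_expression_matrix <- function(matrix, path, subtype_path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  df <- data.frame(feature_id = rownames(matrix$values),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(matrix$values, optional = TRUE))
  write_tsv_precise(df, path)
  write_tsv_precise(data.frame(sample = colnames(matrix$values),
                               subtype = unname(matrix$subtype),
                               stringsAsFactors = FALSE),
                    subtype_path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path, subtype_path,
                                   platform = c("fpkm", "log2fpkm",
                                                "intensity"),
                                   probe_map_path = NULL) {
  platform <- match.arg(platform)
  df <- read_tsv_checked(path)
  if (!"feature_id" %in% names(df))
    stop("read_expression_matrix: missing 'feature_id' column in ", path)
  dup <- which(duplicated(df$feature_id))
  if (length(dup))
    stop("read_expression_matrix: duplicate feature id '",
         df$feature_id[dup[1]], "' at line ", dup[1] + 1L)
  v <- vapply(names(df)[-1],
              function(cn) as_numeric_checked(df[[cn]], cn, path),
              numeric(nrow(df)))
  v <- matrix(v, nrow = nrow(df),
              dimnames = list(df$feature_id, names(df)[-1]))
  sd <- read_tsv_checked(subtype_path)
  pm <- if (!is.null(probe_map_path)) read_tsv_checked(probe_map_path)
  expression_matrix(v, stats::setNames(sd$subtype, sd$sample),
                    platform = platform, probe_map = pm)
}

#' Read gene sets from a long-format annotation file
#'
#' Tab-separated with columns `term` and `id`, one membership per line.
#'
#' @param path File path.
#' @return Named list: term -> character vector of member ids.
#' @export
read_gene_sets <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("term", "id") %in% names(df)))
    stop("read_gene_sets: need columns 'term' and 'id' in ", path)
  split(df$id, df$term)
}

#' Read a plasma-detectability protein list (one id per line)
#'
#' @param path File path.
#' @return Character vector of protein ids.
#' @export
read_plasma_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Read / write PSM tables
#'
#' The on-disk format is the PSM data frame of [simulate_psm_table()]:
#' tab-separated with the fixed feature header and one `reporter_*` column
#' per channel; multiple protein accessions are semicolon-joined.
#'
#' @param psms PSM data frame.
#' @param path File path.
#' @return `read_psm_table` returns the PSM data frame.
#' @export
write_psm_table <- function(psms, path) {
  write_tsv_precise(psms, path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  df <- read_tsv_checked(path)
  check_psm_table(df, features = TRUE)
  df$is_decoy <- as.logical(df$is_decoy)
  df
}

#' Write spectra to a delimited peak-list file
#'
#' Long tab-separated format with columns `scan_id`, `mz`, `intensity`,
#' one row per peak.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path File path.
#' @return `read_peaklist` returns the list of spectra.
#' @export
write_peaklist <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s)
    data.frame(scan_id = s$scan_id, mz = s$mz, intensity = s$intensity,
               stringsAsFactors = FALSE)))
  write_tsv_precise(df, path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("scan_id", "mz", "intensity") %in% names(df)))
    stop("read_peaklist: need columns scan_id, mz, intensity in ", path)
  df$mz <- as_numeric_checked(df$mz, "mz", path)
  df$intensity <- as_numeric_checked(df$intensity, "intensity", path)
  lapply(split(df, factor(df$scan_id, levels = unique(df$scan_id))),
         function(s) spectrum(s$scan_id[1], s$mz, s$intensity))
}

#' Write spectra to a minimal mzML file
#'
#' Serializes MS2 peak lists through the proteomics standards writer of
#' the mzR package; only the fields the pipeline needs (scan id, m/z
#' array, intensity array) are meaningful.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output mzML path.
#' @return The path, invisibly.
#' @export
write_spectra_mzml <- function(spectra, path) {
  n <- length(spectra)
  pks <- lapply(spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(2L, n), polarity = rep(1L, n),
    peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity),
                           numeric(1)),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = rep(34, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = rep(0L, n), precursorMZ = rep(500, n),
    precursorCharge = rep(2L, n), precursorIntensity = rep(1e5, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n),
    mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = vapply(spectra, function(s) s$scan_id, character(1)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Read the minimal spectrum subset from an mzML file
#'
#' Reads scan identifiers, m/z arrays and intensity arrays; all other
#' mzML content is ignored.
#'
#' @param path mzML file path.
#' @return List of [spectrum()] objects.
#' @export
read_mzml_subset <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hdr)), function(i)
    spectrum(hdr$spectrumId[i], pk[[i]][, 1], pk[[i]][, 2]))
}

#' Export a dendrogram in Newick format
#'
#' @param result A `clustering_result` from [hierarchical_cluster()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(result, path) {
  stopifnot(inherits(result, "clustering_result"))
  ape::write.tree(ape::as.phylo(result$hclust), file = path)
  invisible(path)
}

#' Write a ground-truth object as structured text (JSON)
#'
#' @param truth A `ground_truth` list from the simulators.
#' @param path Output file path.
#' @return `read_truth` returns the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
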