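#' TMT six-plex reporter channel definition
#'
#' Channel labels, theoretical reporter m/z values and the extraction
#' window. The default window width of 0.03 Th is the total width of the
#' window scanned around each theoretical reporter m/z, i.e. +/- 0.015 Th.
#'
#' @param labels Ordered channel names.
#' @param theoretical_mz Per-channel theoretical reporter m/z (Th), strictly
#'   increasing.
#' @param window_width Total window width in Th (peaks within
#'   `window_width / 2` of a center are assigned to that channel).
#' @return An object of class `reporter_channels`.
#' @examples
#' reporter_channels()
#' @export
reporter_channels <- function(labels = c("126", "127", "128", "129",
                                         "130", "131"),
                              theoretical_mz = c(126.127726, 127.124761,
                                                 128.134436, 129.131471,
                                                 130.141145, 131.138180),
                              window_width = 0.03) {
  if (length(labels) != length(theoretical_mz))
    stop("reporter_channels: labels and theoretical_mz lengths differ")
  if (is.unsorted(theoretical_mz, strictly = TRUE))
    stop("reporter_channels: theoretical_mz must be strictly increasing")
  if (window_width <= 0)
    stop("reporter_channels: window_width must be > 0")
  if (any(diff(theoretical_mz) <= window_width))
    stop("reporter_channels: extraction windows overlap at this width")
  structure(list(labels = as.character(labels),
                 theoretical_mz = theoretical_mz,
                 window_width = window_width),
            class = "reporter_channels")
}

#' Construct an MS2 spectrum
#'
#' @param scan_id Scan identifier.
#' @param mz Strictly increasing m/z array (Th).
#' @param intensity Nonnegative intensity array of the same length.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(scan_id, mz, intensity) {
  if (length(mz) != length(intensity))
    stop("spectrum: mz and intensity lengths differ")
  if (length(mz) && is.unsorted(mz, strictly = TRUE))
    stop("spectrum: mz must be strictly increasing")
  if (any(intensity < 0))
    stop("spectrum: intensities must be nonnegative")
  structure(list(scan_id = as.character(scan_id), mz = as.numeric(mz),
                 intensity = as.numeric(intensity)),
            class = "spectrum")
}

#' Construct a protein-by-channel quantification table
#'
#' Holds the summed reporter signal ("SN") of each protein in each channel
#' of one TMT set, together with the channel-to-sample design.
#'
#' @param sn Numeric matrix, proteins x channels, nonnegative, with unique
#'   rownames (protein ids) and channel colnames.
#' @param design `sample_design` rows for this set (may be `NULL`).
#' @return An object of class `protein_quant_table`.
#' @export
protein_quant_table <- function(sn, design = NULL) {
  if (!is.matrix(sn) || !is.numeric(sn))
    stop("protein_quant_table: sn must be a numeric matrix")
  if (is.null(rownames(sn)) || anyDuplicated(rownames(sn)))
    stop("protein_quant_table: sn needs unique rownames (protein ids)")
  if (is.null(colnames(sn)))
    stop("protein_quant_table: sn needs channel colnames")
  if (any(sn < 0)) stop("protein_quant_table: sn values must be >= 0")
  if (!is.null(design)) {
    validate_design(design)
    if (!all(colnames(sn) %in% design$channel))
      stop("protein_quant_table: channel(s) ",
           paste(setdiff(colnames(sn), design$channel), collapse = ", "),
           " missing from design")
  }
  structure(list(sn = sn, design = design), class = "protein_quant_table")
}

#' @export
print.protein_quant_table <- function(x, ...) {
  cat("ProteinQuantTable:", nrow(x$sn), "proteins x", ncol(x$sn),
      "channels")
  if (!is.null(x$design)) cat(" (", unique(x$design$set_id), ")")
  cat("\n")
  invisible(x)
}

#' Construct a reference-relative fold-change matrix
#'
#' @param fc Positive matrix of linear fold changes, proteins x
#'   non-reference samples.
#' @param subtype Named character vector (per column) with values `"ASCL1"`
#'   or `"NEUROD1"`.
#' @param set_id Optional named character vector: TMT set of origin per
#'   column.
#' @return An object of class `fold_change_matrix` with elements `fc`,
#'   `log2fc`, `subtype`, `set_id`.
#' @export
fold_change_matrix <- function(fc, subtype, set_id = NULL) {
  if (!is.matrix(fc) || any(!is.finite(fc)) || any(fc <= 0))
    stop("fold_change_matrix: fc must be a finite positive matrix")
  if (is.null(rownames(fc)) || is.null(colnames(fc)))
    stop("fold_change_matrix: fc needs protein rownames and sample colnames")
  subtype <- subtype[colnames(fc)]
  if (any(is.na(subtype)))
    stop("fold_change_matrix: subtype missing for some sample column")
  if (any(subtype == "REF"))
    stop("fold_change_matrix: reference samples must not appear as columns")
  if (!is.null(set_id)) set_id <- set_id[colnames(fc)]
  structure(list(fc = fc, log2fc = log2(fc), subtype = subtype,
                 set_id = set_id),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("FoldChangeMatrix:", nrow(x$fc), "proteins x", ncol(x$fc),
      "samples (", sum(x$subtype == "ASCL1"), "ASCL1 /",
      sum(x$subtype == "NEUROD1"), "NEUROD1 )\n")
  invisible(x)
}

#' Construct an expression matrix with subtype labels
#'
#' Gene (or probe) by sample expression values for transcriptome
#' validation, FPKM-style (nonnegative) or microarray-intensity-style.
#'
#' @param values Numeric matrix, features x samples, with rownames and
#'   colnames.
#' @param subtype Named character vector of per-sample subtype labels.
#' @param platform One of `"fpkm"`, `"log2fpkm"`, `"intensity"`.
#' @param probe_map Optional data frame with columns `probe`, `gene`
#'   covering every row (probe-level platforms).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, subtype,
                              platform = c("fpkm", "log2fpkm", "intensity"),
                              probe_map = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop("expression_matrix: values must be a matrix with dimnames")
  if (any(!is.finite(values)))
    stop("expression_matrix: values must be finite")
  if (platform == "fpkm" && any(values < 0))
    stop("expression_matrix: FPKM-style values must be >= 0")
  subtype <- subtype[colnames(values)]
  if (any(is.na(subtype)))
    stop("expression_matrix: subtype missing for some sample")
  if (!is.null(probe_map)) {
    if (!all(c("probe", "gene") %in% names(probe_map)))
      stop("expression_matrix: probe_map needs columns 'probe' and 'gene'")
  }
  structure(list(values = values, subtype = subtype, platform = platform,
                 probe_map = probe_map),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("ExpressionMatrix (", x$platform, "):", nrow(x$values),
      "features x", ncol(x$values), "samples\n")
  invisible(x)
}
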