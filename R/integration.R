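#' Reference-relative fold changes for one TMT set
#'
#' Replicate channels of the same sample are arithmetically averaged
#' first; then `FC(protein, sample) = mean SN(sample) / mean SN(reference)`
#' with the reference sample identified by the `"REF"` subtype in the
#' design. Proteins with a zero reference average cannot form a ratio and
#' are excluded (listed in the `"excluded"` attribute). Because FC is a
#' ratio within the table, it is invariant to global rescaling of the
#' normalized SN values.
#'
#' @param table A normalized [protein_quant_table()] whose design maps
#'   every channel.
#' @return A [fold_change_matrix()] whose columns are the non-reference
#'   samples of the set.
#' @export
compute_fold_changes <- function(table) {
  stopifnot(inherits(table, "protein_quant_table"))
  design <- table$design
  if (is.null(design))
    stop("compute_fold_changes: table carries no design")
  design <- design[match(colnames(table$sn), design$channel), ]
  if (!any(design$subtype == "REF"))
    stop("compute_fold_changes: no reference (REF) sample in design")
  samples <- unique(design$sample)
  avg <- vapply(samples, function(s)
    rowMeans(table$sn[, design$channel[design$sample == s],
                      drop = FALSE]),
    numeric(nrow(table$sn)))
  if (!is.matrix(avg))  # single-protein table
    avg <- matrix(avg, nrow = 1,
                  dimnames = list(rownames(table$sn), samples))
  ref_sample <- unique(design$sample[design$subtype == "REF"])
  ref <- avg[, ref_sample]
  excluded <- rownames(table$sn)[ref == 0]
  keep <- ref > 0
  non_ref <- setdiff(samples, ref_sample)
  fc <- sweep(avg[keep, non_ref, drop = FALSE], 1, ref[keep], "/")
  subtype <- stats::setNames(
    design$subtype[match(non_ref, design$sample)], non_ref)
  set_id <- stats::setNames(
    design$set_id[match(non_ref, design$sample)], non_ref)
  out <- fold_change_matrix(fc, subtype, set_id)
  attr(out, "excluded") <- excluded
  out
}

#' Merge fold-change matrices over commonly quantified proteins
#'
#' Rows are the intersection of protein ids across all matrices (exact
#' accession match); columns are the union of sample labels with per-set
#' provenance retained. The operation is associative and its row set does
#' not depend on the order of the inputs.
#'
#' @param matrices List of two or more [fold_change_matrix()] objects.
#' @return The merged [fold_change_matrix()].
#' @export
intersect_common_proteins <- function(matrices) {
  if (length(matrices) < 2L)
    stop("intersect_common_proteins: need at least 2 matrices")
  stopifnot(all(vapply(matrices, inherits, logical(1),
                       "fold_change_matrix")))
  common <- Reduce(intersect, lapply(matrices, function(m) rownames(m$fc)))
  if (!length(common))
    stop("intersect_common_proteins: no protein quantified in every set")
  common <- sort(common)
  fc <- do.call(cbind, lapply(matrices, function(m)
    m$fc[common, , drop = FALSE]))
  subtype <- do.call(c, unname(lapply(matrices, function(m) m$subtype)))
  set_id <- do.call(c, unname(lapply(matrices, function(m) {
    if (is.null(m$set_id))
      stats::setNames(rep(NA_character_, ncol(m$fc)), colnames(m$fc))
    else m$set_id
  })))
  if (anyDuplicated(colnames(fc)))
    stop("intersect_common_proteins: duplicate sample label across sets")
  fold_change_matrix(fc, subtype, set_id)
}

#' Restrict a fold-change matrix to plasma-detectable proteins
#'
#' Mirrors the cross-examination of the quantified secretome against a
#' plasma-proteome membership list (e.g. HUPO): only proteins on the list
#' can serve as blood-accessible biomarker candidates.
#'
#' @param matrix A [fold_change_matrix()].
#' @param plasma_ids Character vector of plasma-detectable protein ids.
#' @return The filtered [fold_change_matrix()] (empty, with a warning, if
#'   nothing is retained); the retained count is attached as attribute
#'   `"n_retained"`.
#' @export
filter_plasma_detectable <- function(matrix, plasma_ids) {
  stopifnot(inherits(matrix, "fold_change_matrix"))
  if (!length(plasma_ids))
    stop("filter_plasma_detectable: empty plasma list")
  keep <- rownames(matrix$fc) %in% plasma_ids
  if (!any(keep))
    warning("filter_plasma_detectable: no quantified protein on the ",
            "plasma list")
  out <- matrix
  out$fc <- matrix$fc[keep, , drop = FALSE]
  out$log2fc <- matrix$log2fc[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}
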