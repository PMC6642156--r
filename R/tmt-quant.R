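#' Extract reporter-ion intensities from an MS2 spectrum
#'
#' For each reporter channel, scans a window of total width
#' `channels$window_width` (default 0.03 Th, i.e. +/- 0.015 Th) around the
#' theoretical reporter m/z and returns the maximum intensity among the
#' peaks inside the window, 0 if the window is empty. Intensity ties are
#' broken by proximity to the theoretical m/z.
#'
#' @param spec A [spectrum()].
#' @param channels A [reporter_channels()] definition.
#' @return Named numeric vector of per-channel intensities.
#' @examples
#' sp <- spectrum("s1", c(126.120, 126.130, 127.125),
#'                c(500, 800, 1000))
#' extract_reporter_intensities(sp)
#' @export
extract_reporter_intensities <- function(spec,
                                         channels = reporter_channels()) {
  if (!inherits(spec, "spectrum")) spec <- do.call(spectrum, spec)
  half <- channels$window_width / 2
  if (any(diff(channels$theoretical_mz) <= channels$window_width))
    stop("extract_reporter_intensities: extraction windows overlap")
  out <- stats::setNames(numeric(length(channels$labels)),
                         channels$labels)
  for (j in seq_along(channels$labels)) {
    m0 <- channels$theoretical_mz[j]
    in_win <- which(abs(spec$mz - m0) <= half)
    if (!length(in_win)) next
    ints <- spec$intensity[in_win]
    best <- in_win[ints == max(ints)]
    if (length(best) > 1L)
      best <- best[which.min(abs(spec$mz[best] - m0))]
    out[j] <- spec$intensity[best]
  }
  out
}

#' Sum reporter intensities per protein ("SN" aggregation)
#'
#' The SN value of each protein in each channel is the sum of that
#' channel's reporter intensity over all of the protein's retained PSMs.
#' PSMs shared by several proteins contribute their full intensity to each
#' mapped protein (no razor assignment). Proteins whose total across all
#' channels is zero are dropped.
#'
#' @param psms PSM data frame with `proteins` (semicolon-joined) and
#'   `reporter_*` columns; supply only FDR-retained PSMs.
#' @param design Optional `sample_design` rows for the set.
#' @return A [protein_quant_table()].
#' @export
aggregate_protein_sn <- function(psms, design = NULL) {
  rep_cols <- grep("^reporter_", names(psms), value = TRUE)
  if (!length(rep_cols))
    stop("aggregate_protein_sn: no reporter_* columns in PSM table")
  prot_list <- strsplit(as.character(psms$proteins), ";", fixed = TRUE)
  nrep <- lengths(prot_list)
  idx <- rep(seq_len(nrow(psms)), nrep)
  m <- as.matrix(psms[idx, rep_cols, drop = FALSE])
  sn <- rowsum(m, group = unlist(prot_list))
  colnames(sn) <- sub("^reporter_", "", rep_cols)
  sn <- sn[rowSums(sn) > 0, , drop = FALSE]
  sn <- sn[order(rownames(sn)), , drop = FALSE]
  protein_quant_table(sn, design)
}

#' Normalize channel totals of a quantification table
#'
#' Because equal peptide amounts are labeled per channel, the total
#' reporter intensity of each channel (summed over all quantified proteins)
#' is equalized: channel `c` is scaled by
#' `mean(channel totals) / total(c)`. After scaling all channel totals
#' agree to within 1e-9 relative tolerance and the operation is idempotent.
#'
#' @param table A [protein_quant_table()].
#' @return The normalized [protein_quant_table()]; scaling factors are
#'   attached as attribute `"factors"`.
#' @examples
#' tab <- protein_quant_table(matrix(c(40, 60, 150, 50),
#'                                   2, 2, dimnames = list(c("P1", "P2"),
#'                                                         c("126", "127"))))
#' colSums(normalize_channel_sums(tab)$sn)
#' @export
normalize_channel_sums <- function(table) {
  stopifnot(inherits(table, "protein_quant_table"))
  totals <- colSums(table$sn)
  if (any(totals == 0))
    stop("normalize_channel_sums: channel ",
         paste(colnames(table$sn)[totals == 0], collapse = ", "),
         " has zero total signal")
  factors <- mean(totals) / totals
  table$sn <- sweep(table$sn, 2, factors, "*")
  attr(table, "factors") <- factors
  table
}

#' Pearson correlation between replicate channels
#'
#' Correlation of `log2(SN + offset)` between two channels over all
#' proteins of the table, the replicate-reproducibility check applied to
#' the duplicate channels of a TMT set.
#'
#' @param table A [protein_quant_table()].
#' @param pairs List of length-2 character vectors of channel names.
#' @param log Correlate on the log2 scale (default) or raw scale.
#' @param offset Pseudocount added before the log (default 1).
#' @return Numeric vector of Pearson r, one per pair, named
#'   `"chA vs chB"`.
#' @export
replicate_correlation <- function(table, pairs, log = TRUE, offset = 1) {
  stopifnot(inherits(table, "protein_quant_table"))
  if (nrow(table$sn) < 3L)
    stop("replicate_correlation: need at least 3 proteins")
  vapply(pairs, function(p) {
    if (!all(p %in% colnames(table$sn)))
      stop("replicate_correlation: unknown channel in pair ",
           paste(p, collapse = "/"))
    x <- table$sn[, p[1]]
    y <- table$sn[, p[2]]
    if (log) {
      x <- log2(x + offset)
      y <- log2(y + offset)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("replicate_correlation: zero variance in channel ",
           paste(p[c(stats::sd(x) == 0, stats::sd(y) == 0)],
                 collapse = ", "))
    stats::cor(x, y)
  }, numeric(1)) |>
    stats::setNames(vapply(pairs, paste, character(1), collapse = " vs "))
}
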