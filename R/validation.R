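#' Log-transform an FPKM expression matrix
#'
#' RNA-seq expression values follow a log-normal-like distribution, so
#' clustering and correlation run on `log2(1 + FPKM)`.
#'
#' @param matrix An [expression_matrix()] with platform `"fpkm"`.
#' @return The transformed [expression_matrix()] (platform `"log2fpkm"`).
#' @export
log_transform_fpkm <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$platform != "fpkm")
    stop("log_transform_fpkm: platform is not FPKM-style")
  if (any(matrix$values < 0))
    stop("log_transform_fpkm: negative expression values")
  matrix$values <- log2(1 + matrix$values)
  matrix$platform <- "log2fpkm"
  matrix
}

#' Average probe-level values per gene
#'
#' Microarray intensities (e.g. MAS5 signal values) are summarized as the
#' arithmetic mean of all probes mapping to each gene, per sample.
#'
#' @param matrix An [expression_matrix()] whose `probe_map` covers every
#'   probe row.
#' @return A gene-level [expression_matrix()] with genes in sorted order
#'   and no probe map.
#' @export
probe_to_gene_average <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  pm <- matrix$probe_map
  if (is.null(pm))
    stop("probe_to_gene_average: no probe map present")
  missing <- setdiff(rownames(matrix$values), pm$probe)
  if (length(missing))
    stop("probe_to_gene_average: probe(s) without gene mapping: ",
         paste(missing, collapse = ", "))
  gene <- pm$gene[match(rownames(matrix$values), pm$probe)]
  sums <- rowsum(matrix$values, gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  avg <- sums / counts
  avg <- avg[order(rownames(avg)), , drop = FALSE]
  expression_matrix(avg, matrix$subtype, platform = matrix$platform)
}

#' Welch two-sample t-test
#'
#' Unpaired, two-tailed t-test with the Welch variance correction and
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric sample vectors (each of length >= 2; at least one
#'   group with positive variance).
#' @return A list with `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    stop("welch_t_test: both groups have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pairwise Pearson correlation matrix
#'
#' @param x Numeric matrix.
#' @param axis Correlate `"columns"` (default) or `"rows"` of `x`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_pearson <- function(x, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (axis == "rows") x <- t(x)
  if (nrow(x) < 3L)
    stop("pairwise_pearson: need at least 3 observations per vector")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("pairwise_pearson: zero variance in ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  stats::cor(x)
}

#' Rank genes by correlation with a driver gene
#'
#' Pearson correlation of every gene's expression profile with the driver
#' (itself excluded), ranked descending; ties broken by lexicographic gene
#' id.
#'
#' @param matrix An [expression_matrix()].
#' @param driver Driver gene id (must be a row).
#' @param k Number of genes to return (default 4, the "top four" rule).
#' @return Data frame with columns `gene`, `r`, in rank order.
#' @export
top_correlated_genes <- function(matrix, driver, k = 4L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  if (!driver %in% rownames(v))
    stop("top_correlated_genes: driver '", driver, "' not in matrix")
  if (k >= nrow(v))
    stop("top_correlated_genes: k must be smaller than the gene count")
  if (k <= 0) return(data.frame(gene = character(), r = numeric()))
  others <- v[setdiff(rownames(v), driver), , drop = FALSE]
  r <- apply(others, 1, stats::cor, y = v[driver, ])
  ord <- order(-r, names(r))
  data.frame(gene = names(r)[ord][seq_len(k)],
             r = unname(r[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Agglomerative hierarchical clustering (complete linkage)
#'
#' Rows of `x` are the items clustered. With complete linkage the
#' inter-cluster distance is the maximum pairwise item distance, so merge
#' heights are non-decreasing. Distances are Euclidean by default;
#' `"pearson"` uses `1 - r` for clustering correlation structure.
#'
#' @param x Numeric matrix (items x features) with rownames.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson r).
#' @return An object of class `clustering_result` wrapping the `hclust`
#'   fit (`$hclust`) with `$linkage` and `$distance`.
#' @export
hierarchical_cluster <- function(x, linkage = "complete",
                                 distance = c("euclidean", "pearson")) {
  distance <- match.arg(distance)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("hierarchical_cluster: need at least 2 items")
  if (any(!is.finite(x)))
    stop("hierarchical_cluster: non-finite values in input")
  d <- switch(distance,
              euclidean = stats::dist(x),
              pearson = stats::as.dist(1 - stats::cor(t(x))))
  structure(list(hclust = stats::hclust(d, method = linkage),
                 linkage = linkage, distance = distance),
            class = "clustering_result")
}

#' Cut a clustering into k groups
#'
#' @param result A `clustering_result`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(result, k) {
  stopifnot(inherits(result, "clustering_result"))
  stats::cutree(result$hclust, k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' permutation), expectation approximately 0 under independent random
#' assignment.
#'
#' @param a,b Two partitions of the same items (vectors of equal length).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("adjusted_rand_index: partitions differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Concordance between a k-cut clustering and external labels
#'
#' Quantifies how well the dendrogram separates known classes (e.g. the
#' ASCL1-high vs NEUROD1-high samples) as the adjusted Rand index between
#' the k-cluster assignment and the labels.
#'
#' @param result A `clustering_result`.
#' @param k Number of clusters to cut (>= 2).
#' @param labels Per-item class labels aligned with the clustered items.
#' @return The adjusted Rand index.
#' @export
cluster_concordance <- function(result, k, labels) {
  if (k < 2L) stop("cluster_concordance: k must be >= 2")
  assign <- cut_clusters(result, k)
  if (length(labels) != length(assign))
    stop("cluster_concordance: labels not aligned with clustered items")
  adjusted_rand_index(assign, labels)
}

#' Fisher's exact over-representation test
#'
#' One-sided (enrichment) p-value from the hypergeometric upper tail of
#' the 2x2 table overlap / selected-only / term-only / rest. With several
#' terms, p-values are Benjamini-Hochberg adjusted across terms.
#'
#' @param selected Character vector of selected ids (subset of universe).
#' @param term A character vector (one term) or named list of character
#'   vectors (term id -> member ids), each a subset of the universe.
#' @param universe Character vector of all ids.
#' @return A data frame of class `enrichment_result` with columns `term`,
#'   `a`, `b`, `c`, `d`, `p`, `p_adj`.
#' @examples
#' fisher_enrichment(letters[1:5], letters[1:5], letters[1:20])$p
#' @export
fisher_enrichment <- function(selected, term, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("fisher_enrichment: selected ids outside the universe")
  terms <- if (is.list(term)) term else list(term = term)
  if (is.null(names(terms)) || any(names(terms) == ""))
    names(terms) <- paste0("term", seq_along(terms))
  rows <- lapply(names(terms), function(nm) {
    tm <- unique(terms[[nm]])
    if (!all(tm %in% universe))
      stop("fisher_enrichment: term '", nm, "' has ids outside the ",
           "universe")
    a <- length(intersect(selected, tm))
    b <- length(selected) - a
    cc <- length(tm) - a
    d <- length(universe) - a - b - cc
    # upper-tail hypergeometric: P(overlap >= a)
    p <- stats::phyper(a - 1, length(tm), length(universe) - length(tm),
                       length(selected), lower.tail = FALSE)
    data.frame(term = nm, a = a, b = b, c = cc, d = d, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Scan a DNA sequence for E-box motifs (CANNTG)
#'
#' Reports every (possibly overlapping) position whose 6-mer matches
#' C-A-N-N-T-G on the forward strand; the pattern class is its own reverse
#' complement, so single-strand scanning covers both strands. Positions
#' are 0-based. Fixed pattern positions require an exact C/A/T/G; `N` in
#' the sequence matches only the free middle positions.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @return Data frame with columns `position` (0-based) and `motif` (the
#'   matched 6-mer).
#' @examples
#' scan_ebox("AACAGCTGTT")
#' @export
scan_ebox <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("scan_ebox: invalid character in sequence (allowed: A,C,G,T,N)")
  m <- gregexpr("(?=CA[ACGTN]{2}TG)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(position = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  pos <- as.integer(m)
  data.frame(position = pos - 1L,
             motif = substring(sequence, pos, pos + 5L),
             stringsAsFactors = FALSE)
}

#' Reverse-complement a DNA string
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(sequence),
                                              "")[[1]]), collapse = ""))
}
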