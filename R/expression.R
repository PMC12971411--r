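# Expression: TPM normalisation, tissue/stress profiles, and the
# gene-count versus expression-dosage relationship across genomes.

#' TPM-normalise a counts matrix
#'
#' rate = count / (length in kb); TPM = rate / sum(rates) * 1e6 per sample.
#' A sample with all-zero counts stays all-zero, with a warning.
#'
#' @param counts gene x sample numeric matrix (non-negative).
#' @param lengths named vector of effective gene lengths in bases (> 0);
#'   every row of `counts` must have a length.
#' @return TPM matrix of the same shape.
#' @examples
#' m <- matrix(c(10, 90), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpm(m, c(g1 = 1000, g2 = 2000))
#' @export
tpm <- function(counts, lengths) {
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss) > 0) {
    stopf("no length for gene(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stopf("gene lengths must be > 0")
  if (any(counts < 0)) stopf("counts must be >= 0")
  rates <- counts / (len / 1000)
  totals <- colSums(rates)
  zero <- totals == 0
  if (any(zero)) {
    warnf("sample(s) with zero total counts left all-zero: %s",
          paste(colnames(counts)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  sweep(rates, 2, totals, "/") * 1e6
}

#' Effective gene lengths from a GFF3 annotation
#'
#' Length = total bases covered by the union of a gene's exons (overlapping
#' exons merged).
#'
#' @param gff data frame from [read_gff3()] with `type == "exon"` rows
#'   carrying a `Parent` (mRNA) or gene-id attribute resolvable to genes.
#' @param gene_of optional function mapping an exon's Parent id to its gene
#'   id; default strips a trailing transcript suffix `".t<d>"`.
#' @return named numeric vector of lengths in bases.
#' @export
gene_lengths_from_gff <- function(gff, gene_of = NULL) {
  if (is.null(gene_of)) gene_of <- function(id) sub("\\.t\\d+$", "", id)
  ex <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stopf("no exon features in annotation")
  parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  gene <- gene_of(parent)
  out <- vapply(split(seq_len(nrow(ex)), gene), function(idx) {
    ir <- ex[idx, , drop = FALSE]
    ord <- order(ir$start, ir$end)
    s <- ir$start[ord]
    e <- ir$end[ord]
    total <- 0
    cur_s <- s[1]
    cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= cur_e + 1) {
        cur_e <- max(cur_e, e[i])
      } else {
        total <- total + cur_e - cur_s + 1
        cur_s <- s[i]
        cur_e <- e[i]
      }
    }
    total + cur_e - cur_s + 1
  }, numeric(1))
  out
}

#' Group-wise expression profile of family genes
#'
#' Means across replicates per group (tissue or condition), optionally on
#' the log2(TPM + 1) scale used for heatmap export.
#'
#' @param mat gene x sample expression matrix (TPM).
#' @param meta data frame with `sample` plus the grouping column; every
#'   column of `mat` must appear in `meta$sample`.
#' @param genes character vector of family genes to profile (rows of
#'   `mat`).
#' @param group name of the grouping column in `meta` (e.g. `"tissue"`).
#' @param log2_transform return log2(value + 1)?
#' @return gene x group matrix of means.
#' @export
profile_expression <- function(mat, meta, genes = rownames(mat),
                               group = "tissue", log2_transform = FALSE) {
  stopifnot("sample" %in% names(meta), group %in% names(meta))
  miss <- setdiff(colnames(mat), meta$sample)
  if (length(miss) > 0) {
    stopf("sample(s) missing from metadata: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  g <- meta[[group]][match(colnames(mat), meta$sample)]
  if (anyNA(g)) stopf("unknown %s label for sample(s): %s", group,
                      paste(colnames(mat)[is.na(g)][1]))
  sub <- mat[rownames(mat) %in% genes, , drop = FALSE]
  lv <- sort(unique(g))
  out <- vapply(lv, function(l) {
    rowMeans(sub[, g == l, drop = FALSE])
  }, numeric(nrow(sub)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(sub),
                                       dimnames = list(rownames(sub), lv))
  if (log2_transform) out <- log2(out + 1)
  out
}

#' Per-genome expression-dosage records
#'
#' @param membership orthogroup x genome copy-count matrix (family gene
#'   counts per genome are its column sums).
#' @param total_tpm named numeric vector of per-genome total family TPM for
#'   one tissue.
#' @param pseudocount added inside the log2 (default 1).
#' @return data frame: `genome`, `gene_count`, `total_tpm`, `log2_dosage`.
#' @export
dosage_records <- function(membership, total_tpm, pseudocount = 1) {
  genomes <- intersect(colnames(membership), names(total_tpm))
  data.frame(genome = genomes,
             gene_count = as.integer(colSums(membership)[genomes]),
             total_tpm = as.numeric(total_tpm[genomes]),
             log2_dosage = log2(as.numeric(total_tpm[genomes]) + pseudocount),
             stringsAsFactors = FALSE)
}

#' Correlate family gene count with expression dosage across genomes
#'
#' Pearson correlation between per-genome family gene counts and
#' log2(total family TPM + pseudocount), with a two-sided p-value from the
#' t distribution (n - 2 df). Shares its correlation kernel with
#' [associate()].
#'
#' @param records data frame from [dosage_records()] (columns `gene_count`,
#'   `log2_dosage`).
#' @return list: `r`, `p`, `n`, `reason`.
#' @export
dosage_correlation <- function(records) {
  pearson_kernel(records$gene_count, records$log2_dosage)
}
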