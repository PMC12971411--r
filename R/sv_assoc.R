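# Structural variants: depth filtering, insertion/deletion typing, overlap
# with gene +/- flank windows, presence-expression association, promoter
# extraction and cis-element comparison.

#' Type a structural variant from allele lengths
#'
#' @param ref_len,alt_len reference and alternate allele lengths (>= 1).
#' @return `"insertion"`, `"deletion"`, or `"other"` (vectorised).
#' @export
classify_sv_type <- function(ref_len, alt_len) {
  ifelse(alt_len > ref_len, "insertion",
         ifelse(alt_len < ref_len, "deletion", "other"))
}

#' Depth-filter structural variants
#'
#' A genome's genotype is retained only when its depth is at least
#' `min_depth` (inclusive); variants left with no carrier are dropped.
#'
#' @param sv list from [read_sv_vcf()] (or the generator): `variants`,
#'   `dp`, `carrier`.
#' @param min_depth minimum read depth (default 20).
#' @return the same structure with `carrier` masked and carrier-less
#'   variants removed.
#' @export
filter_svs <- function(sv, min_depth = 20) {
  if (is.null(sv$dp)) stopf("SV set carries no DP matrix")
  carrier <- sv$carrier & sv$dp >= min_depth
  keep <- rowSums(carrier) > 0
  out <- sv
  out$variants <- sv$variants[keep, , drop = FALSE]
  out$carrier <- carrier[keep, , drop = FALSE]
  out$dp <- sv$dp[keep, , drop = FALSE]
  for (f in c("ref", "alt")) if (!is.null(out[[f]])) out[[f]] <- out[[f]][keep]
  out
}

#' Gene windows: gene span extended by a flank
#'
#' @param positions data frame with `gene`, `chrom`, `start`, `end`.
#' @param flank bases added on both sides (default 2000), floored at 1.
#' @return data frame: `gene`, `chrom`, `window_start`, `window_end`.
#' @export
gene_windows <- function(positions, flank = 2000) {
  if (flank < 0) stopf("flank must be >= 0")
  data.frame(gene = positions$gene, chrom = positions$chrom,
             window_start = pmax(positions$start - flank, 1L),
             window_end = positions$end + flank, stringsAsFactors = FALSE)
}

# Reference span affected by an SV: [pos, pos + max(ref_len - 1, 0)].
# An insertion's span is its single anchor base.
sv_span <- function(variants) {
  cbind(start = variants$pos,
        end = variants$pos + pmax(variants$ref_len - 1, 0))
}

#' Does a structural variant overlap a gene window?
#'
#' Closed-interval intersection on 1-based coordinates; FALSE across
#' chromosomes.
#'
#' @param variants data frame with `chrom`, `pos`, `ref_len` (one or more
#'   rows).
#' @param window one-row data frame from [gene_windows()].
#' @return logical vector over variants.
#' @export
overlaps <- function(variants, window) {
  span <- sv_span(variants)
  variants$chrom == window$chrom &
    span[, "start"] <= window$window_end &
    span[, "end"] >= window$window_start
}

#' Per-genome gene-level SV presence
#'
#' A gene is SV-present in a genome when at least one retained variant
#' overlapping its window is carried by that genome.
#'
#' @param sv filtered SV set from [filter_svs()].
#' @param windows data frame from [gene_windows()].
#' @return logical matrix, genes x genomes.
#' @export
sv_gene_presence <- function(sv, windows) {
  genomes <- colnames(sv$carrier)
  out <- matrix(FALSE, nrow(windows), length(genomes),
                dimnames = list(windows$gene, genomes))
  if (nrow(sv$variants) == 0) return(out)
  for (i in seq_len(nrow(windows))) {
    ov <- overlaps(sv$variants, windows[i, , drop = FALSE])
    if (any(ov)) {
      out[i, ] <- apply(sv$carrier[ov, , drop = FALSE], 2, any)
    }
  }
  out
}

# Shared Pearson correlation kernel: r plus two-sided p from the
# t distribution on n - 2 df. Used by both the SV association and the
# expression dosage analysis so the two report identical statistics.
pearson_kernel <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n, reason = "n_too_small"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant_input"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n, reason = "ok")
}

#' Associate SV presence with expression across genomes
#'
#' Pearson correlation between a binary presence vector and expression
#' values over genomes, with a two-sided p-value from the t distribution
#' (n - 2 df). For a binary grouping this is the point-biserial
#' correlation, whose p-value equals the equal-variance two-sample t-test.
#'
#' @param presence binary (or logical) vector over genomes.
#' @param expression numeric expression values over the same genomes.
#' @param alpha significance level (default 0.05).
#' @return list: `r`, `p`, `n`, `significant` (p < alpha), `reason`
#'   (`ok`, `constant_input`, `n_too_small`).
#' @export
associate <- function(presence, expression, alpha = 0.05) {
  if (length(presence) != length(expression)) {
    stopf("presence and expression differ in length (%d vs %d)",
          length(presence), length(expression))
  }
  k <- pearson_kernel(as.numeric(presence), as.numeric(expression))
  k$significant <- !is.na(k$p) && k$p < alpha
  k
}

#' Extract a promoter sequence
#'
#' For a + strand gene, the `length` bases immediately 5' of the gene
#' start; for a - strand gene, the `length` bases immediately 3' of the
#' gene end, reverse-complemented. Truncated (with a warning) at contig
#' edges.
#'
#' @param gene one-row data frame with `gene`, `start`, `end`, `strand`.
#' @param contig contig/chromosome sequence (string).
#' @param length promoter length in bases (default 2000).
#' @return promoter sequence (string), possibly shorter than `length` at a
#'   contig edge.
#' @export
extract_promoter <- function(gene, contig, length = 2000) {
  if (!gene$strand %in% c("+", "-")) {
    stopf("unknown strand '%s' for gene %s", gene$strand, gene$gene)
  }
  clen <- nchar(contig)
  if (gene$start < 1 || gene$end > clen) {
    stopf("gene %s lies outside its contig", gene$gene)
  }
  if (gene$strand == "+") {
    from <- gene$start - length
    to <- gene$start - 1
    if (from < 1) {
      warnf("promoter of %s truncated at contig start (%d of %d bases)",
            gene$gene, max(to, 0), length)
      from <- 1
    }
    if (to < 1) return("")
    substr(contig, from, to)
  } else {
    from <- gene$end + 1
    to <- gene$end + length
    if (to > clen) {
      warnf("promoter of %s truncated at contig end (%d of %d bases)",
            gene$gene, max(clen - from + 1, 0), length)
      to <- clen
    }
    if (from > clen) return("")
    revcomp(substr(contig, from, to))
  }
}

#' Count occurrences of an IUPAC motif on both strands
#'
#' Matches the pattern on the forward strand and its reverse complement on
#' the same coordinates; occurrences are deduplicated by position, so a
#' palindromic motif counts once per site.
#'
#' @param motif IUPAC pattern (string).
#' @param sequence DNA sequence (string).
#' @return integer count.
#' @export
count_motif <- function(motif, sequence) {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", toupper(motif))) {
    stopf("invalid IUPAC symbol in motif '%s'", motif)
  }
  if (nchar(sequence) < nchar(motif) || nchar(sequence) == 0) return(0L)
  subj <- Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(pat), subj, fixed = FALSE))
  length(union(fwd, rev))
}

#' Compare promoter cis-element content between two haplotype sets
#'
#' Counts each motif's occurrences (both strands, position-deduplicated)
#' over each promoter set, ranks elements by combined abundance, and keeps
#' the `top_k` most abundant. When the motif table carries categories, a
#' per-category roll-up of how many of the retained elements each haplotype
#' possesses (count > 0) is included.
#'
#' @param promoters_a,promoters_b character vectors of promoter sequences
#'   (haplotypes A and B).
#' @param motifs data frame from [read_motif_table()].
#' @param top_k number of most-abundant elements retained (default 20).
#' @param labels names of the two haplotype sets.
#' @return list: `elements` (data frame `name`, `category`, counts for both
#'   haplotypes, ranked) and `category_presence` (elements with count > 0
#'   per category per haplotype; NULL without categories).
#' @export
compare_elements <- function(promoters_a, promoters_b, motifs = read_motif_table(),
                             top_k = 20, labels = c("A", "B")) {
  if (nrow(motifs) == 0) stopf("empty motif table")
  count_set <- function(proms, pattern) {
    if (length(proms) == 0) return(0L)
    sum(vapply(proms, function(p) count_motif(pattern, p), integer(1)))
  }
  ca <- vapply(motifs$pattern, count_set, integer(1), proms = promoters_a)
  cb <- vapply(motifs$pattern, count_set, integer(1), proms = promoters_b)
  el <- data.frame(name = motifs$name, category = motifs$category,
                   stringsAsFactors = FALSE)
  el[[labels[1]]] <- ca
  el[[labels[2]]] <- cb
  el <- el[order(-(ca + cb), el$name), , drop = FALSE]
  el <- utils::head(el, top_k)
  rownames(el) <- NULL
  rollup <- NULL
  if (any(!is.na(el$category))) {
    cats <- sort(unique(el$category[!is.na(el$category)]))
    rollup <- data.frame(category = cats)
    for (lb in labels) {
      rollup[[lb]] <- vapply(cats, function(cc) {
        sum(el$category %in% cc & el[[lb]] > 0)
      }, integer(1))
    }
  }
  list(elements = el, category_presence = rollup)
}
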