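# Duplication-mode assignment under the priority cascade
# WGD > TD > PD > TRD > DSD, with an internal dynamic-programming
# collinearity chainer and an outgroup ancestral-locus test.

#' Assign per-chromosome gene ranks
#'
#' Ranks are ordinal positions among genes on the same chromosome (within
#' the same genome when a `genome` column is present), sorted by ascending
#' start; ties broken by end, then gene id.
#'
#' @param positions data frame with `gene`, `chrom`, `start`, `end`
#'   (optionally `genome`, `strand`), e.g. from [gene_positions()].
#' @return the input with a `rank` column added, sorted by chromosome and
#'   rank.
#' @export
rank_genes <- function(positions) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(positions)))
  key <- paste(positions$gene,
               if (is.null(positions$genome)) "" else positions$genome,
               positions$chrom, positions$start, positions$end)
  if (anyDuplicated(key)) {
    stopf("duplicate gene record(s): %s",
          positions$gene[duplicated(key)][1])
  }
  grp <- if (is.null(positions$genome)) positions$chrom
         else paste(positions$genome, positions$chrom)
  ord <- order(grp, positions$start, positions$end, positions$gene)
  positions <- positions[ord, , drop = FALSE]
  grp <- grp[ord]
  positions$rank <- stats::ave(seq_len(nrow(positions)), grp,
                               FUN = seq_along)
  rownames(positions) <- NULL
  positions
}

#' Chain similarity anchors into collinear blocks
#'
#' Dynamic-programming chainer in the MCScanX style: within each chromosome
#' pair, a block is a maximal chain of anchors whose ranks are strictly
#' increasing on the first side and strictly monotone (either direction) on
#' the second, with adjacent rank gaps of at most `max_gap` on both sides.
#' The longest chain is extracted, its anchors removed, and the search
#' repeated while chains of at least `min_block_size` anchors remain.
#' Deterministic: ties are resolved toward the anchor earliest in
#' (rank_a, rank_b) order and parallel orientation.
#'
#' @param anchors data frame with `gene_a`, `gene_b`, `chr_a`, `chr_b`,
#'   `rank_a`, `rank_b` (e.g. from [make_anchors()]).
#' @param min_block_size minimum anchors per block (default 5).
#' @param max_gap maximum adjacent rank gap on either side (default 25).
#' @return data frame of block anchors with `block` id and `orientation`
#'   (`+` parallel, `-` antiparallel) columns; zero rows when no block
#'   qualifies.
#' @export
chain_collinear <- function(anchors, min_block_size = 5, max_gap = 25) {
  need <- c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")
  stopifnot(all(need %in% names(anchors)))
  empty <- cbind(anchors[0, need, drop = FALSE],
                 data.frame(block = integer(), orientation = character()))
  if (nrow(anchors) == 0) return(empty)
  anchors <- anchors[!duplicated(anchors[, need]), , drop = FALSE]
  out <- list()
  bid <- 0L
  for (cp in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    sub <- anchors[paste(anchors$chr_a, anchors$chr_b, sep = "\r") == cp, ,
                   drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    active <- rep(TRUE, nrow(sub))
    repeat {
      idx <- which(active)
      if (length(idx) < min_block_size) break
      best <- best_chain(sub$rank_a[idx], sub$rank_b[idx], max_gap)
      if (length(best$chain) < min_block_size) break
      bid <- bid + 1L
      blk <- sub[idx[best$chain], need, drop = FALSE]
      blk$block <- bid
      blk$orientation <- best$orientation
      out[[bid]] <- blk
      active[idx[best$chain]] <- FALSE
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Longest valid chain over anchors sorted by (rank_a, rank_b); returns the
# member indices and orientation. O(n^2) DP, n = anchors per chromosome pair.
best_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- list(chain = integer(), orientation = "+")
  for (dir in c(1L, -1L)) {
    len <- rep(1L, n)
    pred <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        da <- ra[i] - ra[j]
        db <- dir * (rb[i] - rb[j])
        if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap &&
            len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          pred[i] <- j
        }
      }
    }
    top <- which.max(len)
    if (len[top] > length(best$chain)) {
      chain <- integer(len[top])
      k <- top
      for (p in rev(seq_len(len[top]))) {
        chain[p] <- k
        k <- pred[k]
      }
      best <- list(chain = chain, orientation = if (dir == 1L) "+" else "-")
    }
  }
  best
}

#' Build rank-annotated anchors from homologous pairs
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param pos_a ranked positions (from [rank_genes()]) covering the `gene_a`
#'   side.
#' @param pos_b ranked positions covering the `gene_b` side; defaults to
#'   `pos_a` (intra-genome anchors).
#' @return anchor data frame for [chain_collinear()]. Intra-genome
#'   same-chromosome anchors are canonicalised with `rank_a <= rank_b`.
#' @export
make_anchors <- function(pairs, pos_a, pos_b = pos_a) {
  ia <- match(pairs$gene_a, pos_a$gene)
  ib <- match(pairs$gene_b, pos_b$gene)
  if (any(is.na(ia)) || any(is.na(ib))) {
    bad <- c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)])
    stopf("gene(s) missing from position table: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  a <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  chr_a = pos_a$chrom[ia], chr_b = pos_b$chrom[ib],
                  rank_a = pos_a$rank[ia], rank_b = pos_b$rank[ib],
                  stringsAsFactors = FALSE)
  flip <- a$chr_a == a$chr_b & a$rank_a > a$rank_b
  a[flip, c("gene_a", "gene_b", "rank_a", "rank_b")] <-
    a[flip, c("gene_b", "gene_a", "rank_b", "rank_a")]
  a
}

#' Classify duplication pairs by the WGD > TD > PD > TRD > DSD cascade
#'
#' Each intra-genome homologous pair receives exactly one mode: WGD if the
#' pair is an anchor of an intra-genome collinear block; else TD (tandem)
#' if on one chromosome at rank distance <= `td_max_gap`; else PD
#' (proximal) if at rank distance <= `pd_max_gap`; else TRD (transposed) if
#' exactly one gene of the pair is anchored in a collinear block against
#' the outgroup (the ancestral locus); else DSD (dispersed).
#'
#' @param pairs data frame with `gene_a`, `gene_b` (intra-genome pairs).
#' @param blocks intra-genome blocks from [chain_collinear()].
#' @param outgroup_blocks blocks of genome-vs-outgroup anchors (may have
#'   zero rows when no outgroup is available, in which case no pair can be
#'   TRD).
#' @param positions ranked positions from [rank_genes()] covering all pair
#'   genes.
#' @param td_max_gap maximum rank distance for tandem (default 1:
#'   adjacent).
#' @param pd_max_gap maximum rank distance for proximal (default 10).
#' @return data frame: `gene_a`, `gene_b`, `mode`, `evidence`.
#' @export
classify_duplications <- function(pairs, blocks, outgroup_blocks, positions,
                                  td_max_gap = 1, pd_max_gap = 10) {
  if (nrow(pairs) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      mode = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  ia <- match(pairs$gene_a, positions$gene)
  ib <- match(pairs$gene_b, positions$gene)
  if (any(is.na(ia)) || any(is.na(ib))) {
    stopf("pair gene(s) missing from position table")
  }
  if (!is.null(positions$genome) &&
      any(positions$genome[ia] != positions$genome[ib])) {
    stopf("pair spans two genomes: %s / %s",
          pairs$gene_a[which(positions$genome[ia] != positions$genome[ib])[1]],
          pairs$gene_b[which(positions$genome[ia] != positions$genome[ib])[1]])
  }
  if (any(pairs$gene_a == pairs$gene_b)) stopf("self pair in input")
  blk_keys <- if (nrow(blocks) > 0) pair_key(blocks$gene_a, blocks$gene_b)
              else character()
  blk_id <- if (nrow(blocks) > 0) blocks$block else integer()
  anchored <- if (nrow(outgroup_blocks) > 0) {
    intersect(unique(c(outgroup_blocks$gene_a, outgroup_blocks$gene_b)),
              positions$gene)
  } else character()
  mode <- character(nrow(pairs))
  evidence <- character(nrow(pairs))
  same_chr <- positions$chrom[ia] == positions$chrom[ib]
  rdist <- abs(positions$rank[ia] - positions$rank[ib])
  for (i in seq_len(nrow(pairs))) {
    hit <- match(key[i], blk_keys)
    if (!is.na(hit)) {
      mode[i] <- "WGD"
      evidence[i] <- sprintf("block=%d", blk_id[hit])
    } else if (same_chr[i] && rdist[i] <= td_max_gap) {
      mode[i] <- "TD"
      evidence[i] <- sprintf("rank_dist=%d", rdist[i])
    } else if (same_chr[i] && rdist[i] <= pd_max_gap) {
      mode[i] <- "PD"
      evidence[i] <- sprintf("rank_dist=%d", rdist[i])
    } else {
      in_a <- pairs$gene_a[i] %in% anchored
      in_b <- pairs$gene_b[i] %in% anchored
      if (xor(in_a, in_b)) {
        mode[i] <- "TRD"
        evidence[i] <- sprintf("ancestral=%s",
                               if (in_a) pairs$gene_a[i] else pairs$gene_b[i])
      } else {
        mode[i] <- "DSD"
        evidence[i] <- ""
      }
    }
  }
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             mode = mode, evidence = evidence, stringsAsFactors = FALSE)
}

#' Intra-genome candidate pairs from a similarity table
#'
#' Homolog pairs above the similarity floor (default E <= 1e-10 and
#' identity >= 30%), restricted to genes present in the position table and
#' to pairs within one genome; unordered, deduplicated, self-hits dropped.
#'
#' @param hits data frame from [read_blast6()].
#' @param positions ranked positions (with a `genome` column when the table
#'   spans several genomes).
#' @param max_evalue,min_identity similarity floor.
#' @return data frame: `gene_a`, `gene_b` (gene_a < gene_b).
#' @export
candidate_pairs_from_hits <- function(hits, positions, max_evalue = 1e-10,
                                      min_identity = 30) {
  keep <- hits$evalue <= max_evalue & hits$identity >= min_identity &
    hits$query != hits$subject &
    hits$query %in% positions$gene & hits$subject %in% positions$gene
  h <- hits[keep, , drop = FALSE]
  if (!is.null(positions$genome)) {
    gmap <- positions$genome[match(h$query, positions$gene)]
    gmap2 <- positions$genome[match(h$subject, positions$gene)]
    h <- h[gmap == gmap2, , drop = FALSE]
  }
  a <- pmin(h$query, h$subject)
  b <- pmax(h$query, h$subject)
  keep <- !duplicated(paste(a, b))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Duplication mode x orthogroup category crosstab
#'
#' @param dup_pairs data frame from [classify_duplications()].
#' @param genes data frame mapping `gene` to `og`.
#' @param categories data frame from [og_categories()].
#' @return list with `table` (mode x category counts), `counts` (per-mode
#'   totals), `proportions` (per-mode percent shares, half-up to one
#'   decimal) and `total` pairs.
#' @export
crosstab_mode_by_category <- function(dup_pairs, genes, categories) {
  modes <- c("WGD", "TD", "PD", "TRD", "DSD")
  cats <- c("core", "soft-core", "dispensable", "private")
  og <- genes$og[match(dup_pairs$gene_a, genes$gene)]
  cat <- categories$category[match(og, categories$og)]
  tab <- table(factor(dup_pairs$mode, levels = modes),
               factor(cat, levels = cats))
  counts <- rowSums(tab)
  total <- sum(counts)
  props <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * NA
  list(table = unclass(tab), counts = counts, proportions = props,
       total = total)
}
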