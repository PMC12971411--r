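# Nei-Gojobori (1986) Ka/Ks estimation on protein-guided codon alignments,
# plus selection-class calls and per-orthogroup distributions.

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the number of
#' the three possible single-nucleotide changes that preserve the amino acid,
#' divided by 3; changes into stop codons count as nonsynonymous. S is the
#' sum over positions and N = 3 - S.
#'
#' @param codon a sense codon (3-mer over ACGT).
#' @return named numeric vector `c(N = , S = )`.
#' @examples
#' ng86_sites("TTT")  # S = 1/3
#' ng86_sites("TGG")  # S = 0: tryptophan has no synonymous change
#' @export
ng86_sites <- function(codon) {
  ct <- codon_table()
  if (!(codon %in% ct$codons)) stopf("not a codon: '%s'", codon)
  if (ct$aa[[codon]] == "*") stopf("stop codon '%s' has no NG86 sites", codon)
  ct$sites[codon, ]
}

# Observed synonymous/nonsynonymous differences between two sense codons,
# averaged with equal weight over all minimal mutational pathways that avoid
# stop codons (all pathways if every one passes through a stop).
ng86_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Nd = 0, Sd = 0))
  ct <- codon_table()
  memo_key <- paste0(c1, c2)
  memo <- .codon_cache$diffs
  hit <- memo[[memo_key]]
  if (!is.null(hit)) return(hit)
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  perms <- switch(length(pos),
                  list(pos),
                  list(pos, rev(pos)),
                  {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  walk <- function(order) {
    cur <- n1
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (p in order) {
      nxt <- cur
      nxt[p] <- n2[p]
      aa_cur <- ct$aa[[paste(cur, collapse = "")]]
      aa_nxt <- ct$aa[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") ok <- FALSE
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd, ok)
  }
  res <- vapply(perms, walk, numeric(3))
  use <- res[3, ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(res))
  out <- c(Nd = mean(res[1, use]), Sd = mean(res[2, use]))
  memo[[memo_key]] <- out
  out
}

#' Protein-guided codon alignment of two CDS
#'
#' Globally aligns the two proteins (BLOSUM62, gap opening 10, extension
#' 0.5), back-translates the alignment codon-wise, and masks codon columns
#' that contain a gap. A terminal stop codon on either CDS is trimmed before
#' validation; an internal stop or a CDS/protein translation mismatch is an
#' error.
#'
#' @param prot_a,prot_b protein sequences (strings); if NULL they are derived
#'   by translating the CDS.
#' @param cds_a,cds_b coding sequences (strings), lengths divisible by 3.
#' @param ids length-2 character vector naming the sequences in error
#'   messages.
#' @return an object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (aligned codon vectors, `---` for gaps) and `keep` (logical
#'   mask of gap-free columns).
#' @export
align_codons <- function(prot_a = NULL, prot_b = NULL, cds_a, cds_b,
                         ids = c("a", "b")) {
  prep <- function(cds, prot, id) {
    if (nchar(cds) %% 3 != 0) {
      stopf("CDS of '%s' has length %d, not divisible by 3", id, nchar(cds))
    }
    cod <- split_codons(toupper(cds))
    aa <- translate_codons(cod)
    n <- length(aa)
    if (aa[n] == "*") {
      cod <- cod[-n]
      aa <- aa[-n]
    }
    if (any(aa == "*")) stopf("internal stop codon in CDS of '%s'", id)
    if (!is.null(prot)) {
      prot <- sub("\\*$", "", toupper(prot))
      if (paste(aa, collapse = "") != prot) {
        stopf("CDS of '%s' does not translate to its protein", id)
      }
    }
    list(cod = cod, prot = paste(aa, collapse = ""))
  }
  a <- prep(cds_a, prot_a, ids[1])
  b <- prep(cds_b, prot_b, ids[2])
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$prot), Biostrings::AAString(b$prot),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  back <- function(gapped, cod) {
    out <- character(length(gapped))
    k <- 0L
    for (i in seq_along(gapped)) {
      if (gapped[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- cod[k]
      }
    }
    out
  }
  ca <- back(ga, a$cod)
  cb <- back(gb, b$cod)
  structure(list(codons_a = ca, codons_b = cb,
                 keep = ga != "-" & gb != "-", ids = ids),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment (%s vs %s): %d columns, %d retained\n",
              x$ids[1], x$ids[2], length(x$keep), sum(x$keep)))
  invisible(x)
}

#' NG86 Ka/Ks estimate for an aligned codon pair
#'
#' Site totals N and S are averaged over the two sequences; observed
#' differences are resolved by equal-weight averaging over minimal
#' mutational pathways avoiding stop codons; proportions are corrected with
#' the Jukes-Cantor formula d = -(3/4) log(1 - 4p/3), undefined for
#' p >= 3/4. The ratio is NA when Ks = 0 or a correction is undefined, with
#' a machine-readable reason code.
#'
#' @param x a `codon_alignment`, a `codon_pair_sim`, or a CDS string (with
#'   `y` the second CDS string of equal length and no internal stops).
#' @param y optional second CDS string when `x` is a string.
#' @return an object of class `kaks_estimate`: list with `ka`, `ks`,
#'   `ratio`, `N`, `S`, `Nd`, `Sd`, `n_codons`, `class`
#'   (positive/purifying/neutral/NA) and `reason`
#'   (`ok`, `ks_zero`, `correction_undefined`, `no_columns`).
#' @examples
#' est <- ng86_pair("AAAGTT", "AGAGTA")
#' est$Nd  # 1 nonsynonymous difference (AAA->AGA)
#' @export
ng86_pair <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) {
    ca <- x$codons_a[x$keep]
    cb <- x$codons_b[x$keep]
  } else if (inherits(x, "codon_pair_sim")) {
    ca <- x$codons_a
    cb <- x$codons_b
  } else if (is.character(x) && is.character(y)) {
    ca <- split_codons(toupper(x))
    cb <- split_codons(toupper(y))
    if (length(ca) != length(cb)) {
      stopf("unaligned CDS of different codon lengths (%d vs %d); use align_codons()",
            length(ca), length(cb))
    }
    n <- length(ca)
    if (n > 1 && translate_codons(ca[n]) == "*" && translate_codons(cb[n]) == "*") {
      ca <- ca[-n]
      cb <- cb[-n]
    }
    if (any(translate_codons(ca) == "*") || any(translate_codons(cb) == "*")) {
      stopf("internal stop codon in CDS pair")
    }
  } else {
    stopf("x must be a codon_alignment, codon_pair_sim, or CDS string pair")
  }
  n_cod <- length(ca)
  empty <- function(reason) {
    structure(list(ka = NA_real_, ks = NA_real_, ratio = NA_real_,
                   N = NA_real_, S = NA_real_, Nd = NA_real_, Sd = NA_real_,
                   n_codons = n_cod, class = NA_character_, reason = reason),
              class = "kaks_estimate")
  }
  if (n_cod == 0) return(empty("no_columns"))
  ct <- codon_table()
  bad <- c(ca, cb)[!(c(ca, cb) %in% ct$sense)]
  if (length(bad) > 0) stopf("non-sense codon in alignment: %s", bad[1])
  sa <- ct$sites[ca, , drop = FALSE]
  sb <- ct$sites[cb, , drop = FALSE]
  N <- (sum(sa[, "N"]) + sum(sb[, "N"])) / 2
  S <- (sum(sa[, "S"]) + sum(sb[, "S"])) / 2
  d <- vapply(seq_len(n_cod),
              function(i) ng86_codon_diffs(ca[i], cb[i]), numeric(2))
  Nd <- sum(d["Nd", ])
  Sd <- sum(d["Sd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pN <- Nd / N
  pS <- if (S > 0) Sd / S else 0
  ka <- jc(pN)
  ks <- jc(pS)
  reason <- "ok"
  ratio <- NA_real_
  if (is.na(ka) || is.na(ks)) {
    reason <- "correction_undefined"
  } else if (ks == 0) {
    reason <- "ks_zero"
  } else {
    ratio <- ka / ks
  }
  est <- structure(list(ka = ka, ks = ks, ratio = ratio, N = N, S = S,
                        Nd = Nd, Sd = Sd, n_codons = n_cod,
                        class = NA_character_, reason = reason),
                   class = "kaks_estimate")
  est$class <- classify_selection(est)
  est
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("NG86 estimate over %d codons: Ka = %s, Ks = %s, Ka/Ks = %s (%s)\n",
              x$n_codons, format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$ratio, digits = 4),
              if (is.na(x$class)) x$reason else x$class))
  invisible(x)
}

#' Selection class of a Ka/Ks estimate
#'
#' @param estimate a `kaks_estimate`, or a numeric Ka/Ks ratio.
#' @return `"positive"` (ratio > 1), `"purifying"` (< 1), `"neutral"` (= 1),
#'   or NA when the ratio is undefined.
#' @export
classify_selection <- function(estimate) {
  ratio <- if (inherits(estimate, "kaks_estimate")) estimate$ratio else estimate
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio > 1, "positive",
                ifelse(ratio < 1, "purifying", "neutral")))
}

#' Ka/Ks distributions per orthogroup
#'
#' Estimates Ka/Ks for every unordered cross-genome gene pair inside each
#' orthogroup (genes of the same genome are duplication pairs, handled by
#' the duplication module, and are skipped here). Orthogroups present in a
#' single genome yield no rows.
#'
#' @param genes data frame with columns `gene`, `genome`, `og`.
#' @param cds named character vector of CDS (names = gene ids).
#' @param prot optional named character vector of proteins; translated from
#'   the CDS when absent.
#' @param max_pairs_per_og optional cap on pairs per orthogroup (pairs are
#'   taken in deterministic lexicographic order); Inf for all.
#' @return data frame: `og`, `gene_a`, `gene_b`, `ka`, `ks`, `ratio`,
#'   `class`, `reason`.
#' @export
og_kaks_distribution <- function(genes, cds, prot = NULL,
                                 max_pairs_per_og = Inf) {
  stopifnot(all(c("gene", "genome", "og") %in% names(genes)))
  miss <- setdiff(genes$gene, names(cds))
  if (length(miss) > 0) {
    stopf("no CDS for gene(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  }
  rows <- list()
  for (og in sort(unique(genes$og))) {
    gg <- genes[genes$og == og, , drop = FALSE]
    gg <- gg[order(gg$gene), , drop = FALSE]
    if (length(unique(gg$genome)) < 2) next
    cmb <- utils::combn(nrow(gg), 2)
    cross <- gg$genome[cmb[1, ]] != gg$genome[cmb[2, ]]
    cmb <- cmb[, cross, drop = FALSE]
    if (ncol(cmb) > max_pairs_per_og) {
      cmb <- cmb[, seq_len(max_pairs_per_og), drop = FALSE]
    }
    for (k in seq_len(ncol(cmb))) {
      ga <- gg$gene[cmb[1, k]]
      gb <- gg$gene[cmb[2, k]]
      aln <- align_codons(
        prot_a = if (is.null(prot)) NULL else prot[[ga]],
        prot_b = if (is.null(prot)) NULL else prot[[gb]],
        cds_a = cds[[ga]], cds_b = cds[[gb]], ids = c(ga, gb))
      est <- ng86_pair(aln)
      rows[[length(rows) + 1L]] <- data.frame(
        og = og, gene_a = ga, gene_b = gb,
        ka = est$ka, ks = est$ks, ratio = est$ratio,
        class = est$class, reason = est$reason,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(og = character(), gene_a = character(),
                      gene_b = character(), ka = numeric(), ks = numeric(),
                      ratio = numeric(), class = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
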