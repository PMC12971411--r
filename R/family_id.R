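# Family identification: domain E-value filter, global-identity filter
# against reference proteins, PSPG-motif typing (typical/atypical), nearest
# labelled-reference group assignment, and deterministic family naming.

#' Filter genes by domain-hit E-value
#'
#' Keeps every gene with at least one domain hit at E-value <= cutoff
#' (set semantics: each gene reported once).
#'
#' @param hits data frame from [read_domtbl()] (columns `gene`, `evalue`).
#' @param cutoff E-value cutoff (default 1e-5).
#' @return character vector of unique gene ids, sorted.
#' @export
filter_domain_hits <- function(hits, cutoff = 1e-5) {
  if (cutoff <= 0) stopf("E-value cutoff must be > 0")
  stopifnot(all(c("gene", "evalue") %in% names(hits)))
  sort(unique(hits$gene[hits$evalue <= cutoff]))
}

#' Global percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5); identity = matching columns / aligned columns, with terminal-gap
#' columns excluded from the denominator.
#'
#' @param a,b protein sequences (strings).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_term <- function(g) {
    res <- which(g != "-")
    seq_along(g) >= min(res) & seq_along(g) <= max(res)
  }
  keep <- non_term(ga) & non_term(gb)
  100 * sum(ga[keep] == gb[keep]) / sum(keep)
}

# Vectorised identities of many candidates against one reference: one
# pairwiseAlignment call, identity from fast accessors. For global
# alignments the insertion/deletion ranges exclude terminal gap runs, so
# matches / (matches + mismatches + indel columns) equals the
# terminal-gap-excluded identity computed by pairwise_identity (verified
# against it in the test suite).
identity_many <- function(candidates, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(toupper(candidates)),
    Biostrings::AAString(toupper(ref)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ins <- sum(IRanges::width(Biostrings::insertion(aln)))
  del <- sum(IRanges::width(Biostrings::deletion(aln)))
  m <- Biostrings::nmatch(aln)
  100 * m / (m + Biostrings::nmismatch(aln) + ins + del)
}

#' Filter candidates by best identity against a reference set
#'
#' A candidate passes when its best global-alignment identity against any
#' reference is strictly greater than the threshold.
#'
#' @param candidates named character vector of candidate proteins.
#' @param references named character vector of reference proteins
#'   (non-empty).
#' @param threshold percent identity threshold in (0, 100); default 50
#'   (strictly greater than).
#' @return character vector of passing candidate names, sorted.
#' @export
identity_filter <- function(candidates, references, threshold = 50) {
  if (length(references) == 0) stopf("empty reference protein set")
  if (length(candidates) == 0) return(character())
  if (threshold <= 0 || threshold >= 100) stopf("threshold must be in (0, 100)")
  best <- rep(0, length(candidates))
  for (ref in references) {
    best <- pmax(best, identity_many(candidates, ref))
  }
  sort(names(candidates)[best > threshold])
}

#' Read a PSPG position-weight model
#'
#' Tab-separated with header `position`, `residues` (accepted residues at
#' that position) and `weight`.
#'
#' @param path file path; defaults to the 44-position consensus model
#'   shipped with the package.
#' @return data frame with attributes used by [classify_pspg()].
#' @export
read_pspg_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pspg_model.tsv", package = "panfam")
  }
  tab <- utils::read.delim(path, colClasses = c("integer", "character",
                                                "numeric"))
  stopifnot(all(c("position", "residues", "weight") %in% names(tab)))
  tab[order(tab$position), , drop = FALSE]
}

# Best sliding-window score of a protein against the position-weight model.
pspg_score <- function(protein, model) {
  width <- nrow(model)
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) < width) return(NA_real_)
  res_sets <- strsplit(model$residues, "")
  best <- 0
  for (s in seq_len(length(aa) - width + 1)) {
    sc <- 0
    for (j in seq_len(width)) {
      if (aa[s + j - 1] %in% res_sets[[j]]) sc <- sc + model$weight[j]
    }
    if (sc > best) best <- sc
  }
  best
}

#' Classify a protein as a typical or atypical family member
#'
#' Typical means the best sliding-window score against the PSPG
#' position-weight model reaches the cutoff (default 60% of the maximal
#' attainable score). Proteins shorter than the motif width are atypical
#' (with a warning).
#'
#' @param protein protein sequence (string).
#' @param model position-weight model from [read_pspg_model()].
#' @param score_cutoff fraction of the maximal score required (in (0, 1]).
#' @return `"typical"` or `"atypical"`.
#' @export
classify_pspg <- function(protein, model = read_pspg_model(),
                          score_cutoff = 0.6) {
  sc <- pspg_score(protein, model)
  if (is.na(sc)) {
    warnf("protein shorter than the %d-residue motif; typed atypical",
          nrow(model))
    return("atypical")
  }
  if (sc >= score_cutoff * sum(model$weight)) "typical" else "atypical"
}

#' Assign a phylogenetic group by nearest labelled reference
#'
#' Returns the group label of the reference with the highest global
#' identity; ties are broken by the lexicographically smallest group label.
#'
#' @param protein protein sequence (string).
#' @param labeled_refs data frame with columns `seq` and `group`.
#' @return a group label.
#' @export
assign_group <- function(protein, labeled_refs) {
  stopifnot(nrow(labeled_refs) > 0,
            all(c("seq", "group") %in% names(labeled_refs)))
  ids <- vapply(labeled_refs$seq, function(ref) pairwise_identity(protein, ref),
                numeric(1))
  cand <- labeled_refs$group[ids == max(ids)]
  sort(cand)[1]
}

#' Group labels for many proteins at once
#'
#' Vectorised version of [assign_group()] (one alignment call per
#' reference instead of per protein/reference pair).
#'
#' @param proteins named character vector of protein sequences.
#' @param labeled_refs data frame with columns `seq` and `group`.
#' @return named character vector of group labels.
#' @export
assign_groups <- function(proteins, labeled_refs) {
  stopifnot(nrow(labeled_refs) > 0)
  ids <- vapply(labeled_refs$seq, function(ref) identity_many(proteins, ref),
                numeric(length(proteins)))
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = length(proteins))
  ord <- order(labeled_refs$group)
  ids <- ids[, ord, drop = FALSE]
  grp <- labeled_refs$group[ord]
  out <- grp[apply(ids, 1, which.max)]  # which.max takes the first (smallest label) tie
  stats::setNames(out, names(proteins))
}

#' Deterministic sequential naming of family orthogroups
#'
#' Orders orthogroups by descending occupancy, then descending total copy
#' number, then orthogroup id, and assigns `<prefix>1`, `<prefix>2`, ...
#'
#' @param membership matrix from [build_membership()].
#' @param prefix label prefix (default `"FAM"`).
#' @return data frame: `og`, `occupancy`, `copies`, `family_name`, in name
#'   order.
#' @export
name_family_ogs <- function(membership, prefix = "FAM") {
  occ <- rowSums(membership > 0)
  copies <- rowSums(membership)
  ord <- order(-occ, -copies, rownames(membership))
  data.frame(og = rownames(membership)[ord],
             occupancy = as.integer(occ[ord]),
             copies = as.integer(copies[ord]),
             family_name = paste0(prefix, seq_along(ord)),
             stringsAsFactors = FALSE)
}
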