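# Codon-level machinery: the standard genetic code, single-nucleotide codon
# neighbourhoods, and a simple omega-scaled codon substitution process used by
# the synthetic-data generator.

.codon_cache <- new.env(parent = emptyenv())

#' Standard-code codon tables
#'
#' Builds (once per session) the codon lookup used throughout the package:
#' all 64 codons, their amino acids under the standard genetic code, the 61
#' sense codons, and for every codon its nine single-nucleotide neighbours
#' annotated as synonymous / nonsynonymous / stop.
#'
#' @return a list with elements `codons`, `aa` (named by codon), `sense`,
#'   and `neigh` (per-codon data frame with columns `target`, `syn`, `stop`).
#' @keywords internal
codon_table <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  neigh <- lapply(codons, function(cd) {
    nts <- strsplit(cd, "")[[1]]
    tg <- character(9L)
    k <- 0L
    for (pos in 1:3) {
      for (b in setdiff(bases, nts[pos])) {
        mut <- nts
        mut[pos] <- b
        k <- k + 1L
        tg[k] <- paste(mut, collapse = "")
      }
    }
    data.frame(target = tg,
               syn  = aa[tg] == aa[cd],
               stop = aa[tg] == "*",
               row.names = NULL)
  })
  names(neigh) <- codons
  sense <- codons[aa != "*"]
  # per-codon NG86 site counts (synonymous fraction of the 9 single-nt
  # changes; changes to stops count as nonsynonymous)
  s_sites <- vapply(sense, function(cd) {
    nb <- neigh[[cd]]
    sum(nb$syn & !nb$stop) / 3
  }, numeric(1))
  sites <- cbind(N = 3 - s_sites, S = s_sites)
  rownames(sites) <- sense
  .codon_cache$tab <- list(codons = codons, aa = aa, sense = sense,
                           neigh = neigh, sites = sites)
  .codon_cache$diffs <- new.env(parent = emptyenv())
  .codon_cache$tab
}

#' Translate codons to amino acids
#'
#' @param codons character vector of 3-mers.
#' @return character vector of single-letter amino acids (`*` for stops).
#' @keywords internal
translate_codons <- function(codons) {
  ct <- codon_table()
  bad <- !(codons %in% ct$codons)
  if (any(bad)) stopf("non-ACGT codon(s): %s", paste(unique(codons[bad]), collapse = ", "))
  unname(ct$aa[codons])
}

split_codons <- function(cds) {
  if (nchar(cds) %% 3 != 0) stopf("CDS length %d not divisible by 3", nchar(cds))
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Evolve codons under an omega-scaled substitution process
#'
#' Each codon evolves independently by a continuous-time process in which
#' every single-nucleotide change to a sense codon occurs at rate 1/3 per
#' unit branch length if synonymous and omega/3 if nonsynonymous; changes
#' into stop codons are forbidden. With omega = 1 the process reduces to a
#' Jukes-Cantor-like neutral per-site process restricted to sense codons,
#' so branch length is (approximately) expected substitutions per
#' nucleotide site.
#'
#' @param codons character vector of sense codons.
#' @param branch_length expected neutral substitutions per nucleotide site.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS), > 0.
#' @param protect logical vector; protected codons are not evolved
#'   (used to keep planted motifs intact).
#' @return the evolved codon vector, with an attribute `events`
#'   (named counts of synonymous and nonsynonymous substitutions).
#' @keywords internal
evolve_codons <- function(codons, branch_length, omega, protect = NULL) {
  if (omega <= 0) stopf("omega must be > 0 (got %g)", omega)
  if (branch_length < 0) stopf("branch_length must be >= 0")
  if (is.null(protect)) protect <- rep(FALSE, length(codons))
  ct <- codon_table()
  n_syn <- 0L
  n_non <- 0L
  if (branch_length > 0) {
    for (i in seq_along(codons)) {
      if (protect[i]) next
      cd <- codons[i]
      tleft <- branch_length
      repeat {
        nb <- ct$neigh[[cd]]
        rates <- ifelse(nb$stop, 0, ifelse(nb$syn, 1, omega)) / 3
        total <- sum(rates)
        if (total <= 0) break
        dt <- stats::rexp(1L, total)
        if (dt > tleft) break
        tleft <- tleft - dt
        j <- sample.int(9L, 1L, prob = rates)
        if (nb$syn[j]) n_syn <- n_syn + 1L else n_non <- n_non + 1L
        cd <- nb$target[j]
      }
      codons[i] <- cd
    }
  }
  attr(codons, "events") <- c(synonymous = n_syn, nonsynonymous = n_non)
  codons
}

#' Simulate a diverged codon-sequence pair at a chosen dN/dS
#'
#' Draws a random ancestral sequence of sense codons and evolves two
#' independent lineages for half the requested branch length each, so that
#' the pairwise divergence equals `branch_length` (in expected neutral
#' substitutions per nucleotide site). Useful as a known-truth input for
#' validating the NG86 estimator.
#'
#' @param n_codons number of codons (>= 50; short sequences make the
#'   estimator too noisy to be informative).
#' @param omega planted dN/dS ratio, > 0.
#' @param branch_length total pairwise divergence, substitutions/site.
#' @param seed optional integer seed; the caller's RNG stream is restored.
#' @return an object of class `codon_pair_sim`: a list with `cds_a`,
#'   `cds_b` (strings), `codons_a`, `codons_b`, `omega`, `branch_length`,
#'   and `events` (substitution counts over both lineages).
#' @examples
#' sim <- simulate_codon_pair(60, omega = 1, branch_length = 0.2, seed = 1)
#' nchar(sim$cds_a) == nchar(sim$cds_b)
#' @export
simulate_codon_pair <- function(n_codons, omega, branch_length, seed = NULL) {
  if (omega <= 0) stopf("omega must be > 0 (got %g)", omega)
  if (n_codons < 50) stopf("n_codons must be >= 50 (got %d)", n_codons)
  if (branch_length < 0) stopf("branch_length must be >= 0")
  ct <- codon_table()
  with_seed(seed, {
    anc <- sample(ct$sense, n_codons, replace = TRUE)
    a <- evolve_codons(anc, branch_length / 2, omega)
    b <- evolve_codons(anc, branch_length / 2, omega)
    ev <- attr(a, "events") + attr(b, "events")
    structure(list(cds_a = paste(a, collapse = ""),
                   cds_b = paste(b, collapse = ""),
                   codons_a = as.character(a), codons_b = as.character(b),
                   omega = omega, branch_length = branch_length,
                   events = ev),
              class = "codon_pair_sim")
  })
}

#' @export
print.codon_pair_sim <- function(x, ...) {
  cat(sprintf("codon pair: %d codons, omega = %g, branch length = %g\n",
              nchar(x$cds_a) / 3, x$omega, x$branch_length))
  cat(sprintf("  substitutions: %d synonymous, %d nonsynonymous\n",
              x$events[["synonymous"]], x$events[["nonsynonymous"]]))
  invisible(x)
}

# Random sense-codon sequence (no stops), used by the generator.
random_codons <- function(n) {
  sample(codon_table()$sense, n, replace = TRUE)
}

# Reverse-complement for plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
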