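# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Longest valid collinear chain by exhaustive depth-first search: first-side
# ranks strictly increasing, second-side ranks strictly monotone in either
# direction, adjacent gaps <= max_gap on both sides.
oracle_longest_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  for (dir in c(1L, -1L)) {
    ext <- function(i, len) {
      if (len > best) best <<- len
      for (j in seq_len(n)) {
        da <- ra[j] - ra[i]
        db <- dir * (rb[j] - rb[i])
        if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap) {
          ext(j, len + 1L)
        }
      }
    }
    for (i in seq_len(n)) ext(i, 1L)
  }
  best
}

# NG86 site counts by brute-force single-mutant enumeration, translated
# with seqinr (independent of the package's codon table).
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- seqinr::translate(seqinr::s2c(codon))
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      maa <- seqinr::translate(seqinr::s2c(mut))
      if (maa == aa && maa != "*") syn <- syn + 1
    }
  }
  c(N = 3 - syn / 3, S = syn / 3)
}

# All 61 sense codons, via seqinr.
oracle_sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  cods[vapply(cods, function(cd) seqinr::translate(seqinr::s2c(cd)) != "*",
              logical(1))]
}
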