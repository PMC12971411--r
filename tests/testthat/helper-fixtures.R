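# Shared fixtures: one default bundle per test run (generation is the
# expensive step), plus a small/fast generator configuration for tests that
# need fresh bundles.

.fixture_env <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    b <- generate_pangenome(pangenome_config(), seed = 42)
    .fixture_env$bundle <- plant_sv_effects(b, seed = 43)
  }
  .fixture_env$bundle
}

# Identify/pan stages on the shared bundle, computed once.
shared_stages <- function() {
  if (is.null(.fixture_env$stages)) {
    b <- shared_bundle()
    par <- panfam:::default_params()
    fam <- panfam:::stage_identify(b, par)
    pan <- panfam:::stage_pan(b, fam, par, seed = 42)
    .fixture_env$stages <- list(family = fam, pan = pan, par = par)
  }
  .fixture_env$stages
}

# Duplication-stage artifacts on the shared bundle, computed once.
shared_dup <- function() {
  if (is.null(.fixture_env$dup)) {
    b <- shared_bundle()
    st <- shared_stages()
    positions <- rank_genes(st$family$genes)
    pairs <- candidate_pairs_from_hits(b$hits_self, positions)
    blocks <- chain_collinear(make_anchors(pairs, positions))
    og_pos <- rank_genes(b$outgroup_positions)
    og_anchors <- make_anchors(
      data.frame(gene_a = b$hits_outgroup$query,
                 gene_b = b$hits_outgroup$subject),
      positions, og_pos)
    out_blocks <- chain_collinear(og_anchors)
    classified <- classify_duplications(pairs, blocks, out_blocks, positions)
    .fixture_env$dup <- list(positions = positions, pairs = pairs,
                             blocks = blocks, out_blocks = out_blocks,
                             classified = classified)
  }
  .fixture_env$dup
}

# A smaller, faster configuration (fewer genomes, shorter genes).
# With 70-codon genes the degraded motif region dominates the sequence, so
# atypical members are left out of the small bundles.
small_config <- function(...) {
  pangenome_config(n_genomes = 5, n_codons = 70, n_atypical = 0,
                   og_spec = data.frame(
                     category = c("core", "soft-core", "dispensable",
                                  "private"),
                     n = c(12L, 4L, 16L, 2L),
                     copy_min = 1L, copy_max = c(1L, 1L, 2L, 1L)),
                   ...)
}

# Toy ranked positions on one genome: n genes on one chromosome, in order.
toy_positions <- function(n, genome = "G", chrom = "c1") {
  rank_genes(data.frame(gene = sprintf("g%02d", seq_len(n)),
                        genome = genome, chrom = chrom,
                        start = seq_len(n) * 1000,
                        end = seq_len(n) * 1000 + 500,
                        strand = "+", stringsAsFactors = FALSE))
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
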