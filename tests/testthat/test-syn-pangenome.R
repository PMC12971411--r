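test_that("configuration invariants are enforced", {
  expect_error(pangenome_config(n_genomes = 3), "n_genomes")
  expect_error(pangenome_config(og_spec = data.frame(
    category = "core", n = 1L, copy_min = 2L, copy_max = 1L)), "copy range")
  expect_error(pangenome_config(omega_grid = c(1, -0.5)), "omega")
  expect_error(pangenome_config(sv_spec = list(effect = -1)), "effect")
  expect_error(pangenome_config(dup_spec = c(WGD = 3L, TD = 1L, PD = 1L,
                                             TRD = 1L, DSD = 1L)), "WGD")
})

test_that("identical config and seed give identical bundles and files", {
  b1 <- generate_pangenome(small_config(), seed = 11)
  b2 <- generate_pangenome(small_config(), seed = 11)
  expect_identical(b1$cds, b2$cds)
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$truth, b2$truth)
  b1 <- plant_sv_effects(b1, seed = 12)
  b2 <- plant_sv_effects(b2, seed = 12)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a full-occupancy orthogroup appears in every genome", {
  b <- shared_bundle()
  core <- b$truth$categories$og[b$truth$categories$category == "core"]
  for (og in core) {
    expect_setequal(unique(b$og_long$genome[b$og_long$og == og]), b$genomes)
  }
})

test_that("written bundle round-trips through the project readers", {
  b <- generate_pangenome(small_config(), seed = 13)
  b <- plant_sv_effects(b, seed = 14)
  dir <- file.path(tempdir(), "bundle_rt")
  write_bundle(b, dir)
  g <- b$genomes[2]
  gff <- read_gff3(file.path(dir, sprintf("%s.gff3", g)))
  pos <- gene_positions(gff)
  want <- b$genes[b$genes$genome == g, c("gene", "chrom", "start", "end",
                                         "strand")]
  got <- pos[match(want$gene, pos$gene), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  cds <- read_fasta(file.path(dir, sprintf("%s.cds.fa", g)), "dna")
  expect_identical(cds[want$gene], b$cds[want$gene])
  og <- read_orthogroups(file.path(dir, "Orthogroups.tsv"))
  got_og <- og[order(og$og, og$genome, og$gene), ]
  want_og <- b$og_long[order(b$og_long$og, b$og_long$genome,
                             b$og_long$gene), ]
  rownames(got_og) <- rownames(want_og) <- NULL
  expect_identical(got_og, want_og)
  sv <- read_sv_vcf(file.path(dir, "svs.vcf"))
  expect_equal(sv$variants$pos, b$sv$variants$pos)
  expect_equal(sv$variants$type, b$sv$variants$type)
  expect_equal(unname(sv$dp[, b$genomes]), unname(b$sv$dp[, b$genomes]))
  expect_equal(unname(sv$carrier[, b$genomes]),
               unname(b$sv$carrier[, b$genomes]))
  hits <- read_domtbl(file.path(dir, "domtbl.tsv"))
  expect_setequal(hits$gene, b$domtbl$gene)
  unlink(dir, recursive = TRUE)
})

test_that("planted dispensable orthogroups are classified dispensable", {
  cfg <- pangenome_config(
    n_genomes = 10, n_codons = 70,
    og_spec = data.frame(category = c("core", "dispensable"),
                         n = c(3L, 10L), copy_min = 1L, copy_max = 1L),
    dup_spec = c(WGD = 0L, TD = 0L, PD = 0L, TRD = 0L, DSD = 0L),
    n_atypical = 0, n_decoys = 0)
  b <- generate_pangenome(cfg, seed = 5)
  m <- build_membership(b$og_long, b$genes$gene, genomes = b$genomes)
  cats <- og_categories(m)
  disp <- b$truth$categories$og[b$truth$categories$category == "dispensable"]
  expect_length(disp, 10)
  expect_true(all(cats$category[match(disp, cats$og)] == "dispensable"))
})

test_that("codon pair simulation honours its contracts", {
  expect_error(simulate_codon_pair(60, omega = 0, branch_length = 0.1),
               "omega")
  expect_error(simulate_codon_pair(10, omega = 1, branch_length = 0.1),
               "n_codons")
  s0 <- simulate_codon_pair(60, omega = 1, branch_length = 0, seed = 1)
  expect_identical(s0$cds_a, s0$cds_b)
  s1 <- simulate_codon_pair(80, omega = 0.5, branch_length = 0.3, seed = 2)
  s2 <- simulate_codon_pair(80, omega = 0.5, branch_length = 0.3, seed = 2)
  expect_identical(s1$cds_a, s2$cds_a)
  expect_identical(s1$cds_b, s2$cds_b)
  # no stop codons ever emitted
  expect_false(any(panfam:::translate_codons(s1$codons_a) == "*"))
  expect_false(any(panfam:::translate_codons(s1$codons_b) == "*"))
  expect_equal(nchar(s1$cds_a), nchar(s1$cds_b))
  expect_equal(nchar(s1$cds_a) %% 3, 0)
})

test_that("depth values below the filter threshold remove every variant", {
  b <- generate_pangenome(small_config(), seed = 21)
  b <- plant_sv_effects(b, sv_spec = list(dp_low_frac = 1), seed = 22)
  expect_true(all(b$sv$dp < 20))
  kept <- filter_svs(b$sv, min_depth = 20)
  expect_equal(nrow(kept$variants), 0)
})

test_that("the generator seed does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(simulate_codon_pair(60, 1, 0.1, seed = 7))
  after <- runif(3)
  expect_identical(before, after)
})
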