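toy_sv <- function(dp, carrier, chrom = "c1", pos = 9500, ref_len = 301,
                   alt_len = 1) {
  n <- length(dp)
  list(variants = data.frame(chrom = chrom, pos = pos, id = "SV1",
                             ref_len = ref_len, alt_len = alt_len,
                             type = classify_sv_type(ref_len, alt_len)),
       dp = matrix(dp, 1, n, dimnames = list("SV1", sprintf("G%d", 1:n))),
       carrier = matrix(carrier, 1, n,
                        dimnames = list("SV1", sprintf("G%d", 1:n))))
}

test_that("variant typing follows allele lengths", {
  expect_equal(classify_sv_type(1, 350), "insertion")
  expect_equal(classify_sv_type(500, 1), "deletion")
  expect_equal(classify_sv_type(5, 5), "other")
})

test_that("depth filtering is inclusive at the threshold and row-wise", {
  kept <- filter_svs(toy_sv(dp = c(20, 20), carrier = c(TRUE, TRUE)))
  expect_equal(nrow(kept$variants), 1)
  gone <- filter_svs(toy_sv(dp = c(19, 19), carrier = c(TRUE, TRUE)))
  expect_equal(nrow(gone$variants), 0)
  mixed <- filter_svs(toy_sv(dp = c(25, 10), carrier = c(TRUE, TRUE)))
  expect_equal(unname(mixed$carrier[1, ]), c(TRUE, FALSE))
  nodp <- toy_sv(dp = c(25, 25), carrier = c(TRUE, TRUE))
  nodp$dp <- NULL
  expect_error(filter_svs(nodp), "DP")
})

test_that("window overlap uses closed intervals on the affected span", {
  gene <- data.frame(gene = "g", chrom = "c1", start = 5000, end = 8000)
  w <- gene_windows(gene, flank = 2000)
  expect_equal(w$window_start, 3000)
  expect_equal(w$window_end, 10000)
  del <- toy_sv(c(30, 30), c(TRUE, TRUE), pos = 9500, ref_len = 301)
  expect_true(overlaps(del$variants, w))
  ins_out <- toy_sv(c(30, 30), c(TRUE, TRUE), pos = 2999, ref_len = 1,
                    alt_len = 100)
  expect_false(overlaps(ins_out$variants, w))
  ins_in <- toy_sv(c(30, 30), c(TRUE, TRUE), pos = 3000, ref_len = 1,
                   alt_len = 100)
  expect_true(overlaps(ins_in$variants, w))
  del_left <- toy_sv(c(30, 30), c(TRUE, TRUE), pos = 1000, ref_len = 2501)
  expect_true(overlaps(del_left$variants, w))   # spans [1000, 3500]
  del_short <- toy_sv(c(30, 30), c(TRUE, TRUE), pos = 1000, ref_len = 1999)
  expect_false(overlaps(del_short$variants, w)) # spans [1000, 2998]
  other_chr <- toy_sv(c(30, 30), c(TRUE, TRUE), chrom = "c2", pos = 9500)
  expect_false(overlaps(other_chr$variants, w))
  # flank 0 reduces to gene-body overlap
  w0 <- gene_windows(gene, flank = 0)
  expect_false(overlaps(toy_sv(c(30, 30), c(TRUE, TRUE), pos = 4000,
                               ref_len = 500)$variants, w0))
  expect_true(overlaps(toy_sv(c(30, 30), c(TRUE, TRUE), pos = 4000,
                              ref_len = 1001)$variants, w0))
})

test_that("gene-level presence requires a retained overlapping carrier", {
  sv <- filter_svs(toy_sv(dp = c(30, 10, 30), carrier = c(TRUE, TRUE, FALSE),
                          pos = 9500, ref_len = 301))
  w <- gene_windows(data.frame(gene = "g", chrom = "c1",
                               start = 5000, end = 8000))
  pres <- sv_gene_presence(sv, w)
  expect_equal(unname(pres["g", ]), c(TRUE, FALSE, FALSE))
})

test_that("association matches the closed-form correlation", {
  a <- associate(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(a$r, 2 / sqrt(5))
  ct <- stats::cor.test(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(a$p, ct$p.value, tolerance = 1e-12)
  expect_equal(associate(c(1, 1, 1, 1), c(1, 2, 3, 4))$reason,
               "constant_input")
  expect_error(associate(c(0, 1), c(1, 2, 3)), "length")
})

test_that("point-biserial p equals the equal-variance t-test p", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    pres <- numeric(n)
    pres[sample(n, sample(2:(n - 2), 1))] <- 1
    y <- rnorm(n, mean = 2 + pres, sd = runif(1, 0.5, 2))
    a <- associate(pres, y)
    tt <- stats::t.test(y[pres == 1], y[pres == 0], var.equal = TRUE)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("type-I error is nominal and planted effects are detected", {
  sim <- simulate_sv_association(400, 20, effect = 0, seed = 77)
  p <- vapply(1:400, function(i) {
    associate(sim$presence[i, ], sim$expression[i, ])$p
  }, numeric(1))
  fpr <- mean(p < 0.05, na.rm = TRUE)
  expect_lte(fpr, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  pow <- simulate_sv_association(5, 20, effect_genes = 1, effect = 400,
                                 seed = 78)
  a <- associate(pow$presence[1, ], pow$expression[1, ])
  expect_lt(a$p, 0.05)
})

test_that("promoters are extracted strand-aware with edge truncation", {
  set.seed(11)
  contig <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                  collapse = "")
  plus <- data.frame(gene = "gp", start = 3001, end = 3600, strand = "+")
  expect_equal(extract_promoter(plus, contig, 2000),
               substr(contig, 1001, 3000))
  minus <- data.frame(gene = "gm", start = 101, end = 500, strand = "-")
  got <- extract_promoter(minus, contig, 2000)
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 501, 2500))))
  expect_equal(got, oracle)
  short <- data.frame(gene = "gs", start = 100, end = 400, strand = "+")
  expect_warning(p99 <- extract_promoter(short, contig, 2000), "truncated")
  expect_equal(nchar(p99), 99)
  bad <- data.frame(gene = "gb", start = 100, end = 400, strand = ".")
  expect_error(extract_promoter(bad, contig), "strand")
})

test_that("motif counting is strand-aware and deduplicates palindromes", {
  expect_equal(count_motif("TATA", "CCTATACC"), 1L)
  expect_equal(count_motif("CACGTG", "AACACGTGAA"), 1L)  # palindrome: once
  # non-palindromic motif present only on the minus strand is still found
  expect_equal(count_motif("GGTCCAT", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("AAGGTCCATAA")))), 1L)
  expect_equal(count_motif("RCCGAC", "TACCGACT"), 1L)  # IUPAC R matches A
  expect_error(count_motif("ACGZ", "ACGT"), "IUPAC")
  expect_equal(count_motif("TATA", "GC"), 0L)
})

test_that("element comparison ranks by combined abundance with roll-ups", {
  motifs <- data.frame(name = c("m1", "m2", "m3"),
                       pattern = c("TATA", "CCAAT", "ACGTGGC"),
                       category = c("growth", "growth", "hormone"))
  pa <- c("TTTATAGGCCAATGG", "CCTATACC")
  pb <- c("GGACGTGGCTT")
  cmp <- compare_elements(pa, pb, motifs, top_k = 2, labels = c("HD", "TGY"))
  expect_equal(nrow(cmp$elements), 2)
  expect_equal(cmp$elements$name[1], "m1")  # 2 TATA occurrences combined
  expect_equal(cmp$elements$HD[cmp$elements$name == "m1"], 2L)
  expect_true(all(c("HD", "TGY") %in% names(cmp$category_presence)))
  empty <- compare_elements(character(), pb, motifs, top_k = 3)
  expect_true(all(empty$elements$A == 0))
  expect_error(compare_elements(pa, pb, motifs[0, ]), "empty motif")
})
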