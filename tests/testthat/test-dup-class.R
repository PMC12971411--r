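test_that("gene ranks are per chromosome, ordered by start", {
  pos <- data.frame(gene = c("a", "b", "c", "d"),
                    chrom = c("c1", "c1", "c1", "c2"),
                    start = c(500, 100, 900, 50),
                    end = c(600, 200, 950, 80),
                    strand = "+")
  r <- rank_genes(pos)
  expect_equal(r$rank[match(c("a", "b", "c", "d"), r$gene)], c(2, 1, 3, 1))
  one <- rank_genes(pos[1, ])
  expect_equal(one$rank, 1)
  expect_error(rank_genes(rbind(pos, pos[1, ])), "duplicate")
})

test_that("collinearity chainer respects the size floor and both orientations", {
  mk <- function(ra, rb) {
    data.frame(gene_a = sprintf("a%d", seq_along(ra)),
               gene_b = sprintf("b%d", seq_along(ra)),
               chr_a = "c1", chr_b = "c2", rank_a = ra, rank_b = rb)
  }
  expect_equal(nrow(chain_collinear(mk(1:4, 11:14), min_block_size = 5)), 0)
  par5 <- chain_collinear(mk(1:5, 11:15), min_block_size = 5, max_gap = 25)
  expect_equal(nrow(par5), 5)
  expect_equal(unique(par5$orientation), "+")
  anti <- chain_collinear(mk(1:5, 15:11), min_block_size = 5, max_gap = 25)
  expect_equal(nrow(anti), 5)
  expect_equal(unique(anti$orientation), "-")
  # a gap larger than max_gap breaks the chain
  broken <- chain_collinear(mk(c(1:4, 40), c(11:14, 50)),
                            min_block_size = 5, max_gap = 25)
  expect_equal(nrow(broken), 0)
})

test_that("chainer agrees with exhaustive search on random anchor sets", {
  set.seed(7)
  for (case in 1:60) {
    n <- sample(2:10, 1)
    ra <- sample(1:14, n, replace = TRUE)
    rb <- sample(1:14, n, replace = TRUE)
    gap <- sample(c(3, 10, 25), 1)
    anchors <- data.frame(gene_a = sprintf("a%d", 1:n),
                          gene_b = sprintf("b%d", 1:n),
                          chr_a = "x", chr_b = "y",
                          rank_a = ra, rank_b = rb)
    blocks <- chain_collinear(anchors, min_block_size = 1, max_gap = gap)
    got <- max(table(blocks$block))
    expect_equal(unname(got), oracle_longest_chain(ra, rb, gap),
                 info = sprintf("case %d", case))
  }
})

test_that("the cascade assigns each mode from its own evidence", {
  pos <- rank_genes(data.frame(
    gene = sprintf("g%02d", 1:12), genome = "G",
    chrom = rep(c("c1", "c2"), each = 6),
    start = rep(1:6 * 1000, 2), end = rep(1:6 * 1000 + 500, 2),
    strand = "+"))
  blocks <- data.frame(gene_a = "g01", gene_b = "g07",
                       chr_a = "c1", chr_b = "c2",
                       rank_a = 1, rank_b = 1, block = 1, orientation = "+")
  outg <- data.frame(gene_a = "g03", gene_b = "out1",
                     chr_a = "c1", chr_b = "oc1",
                     rank_a = 3, rank_b = 1, block = 1, orientation = "+")
  pairs <- data.frame(
    gene_a = c("g01", "g01", "g02", "g03", "g04"),
    gene_b = c("g07", "g02", "g05", "g08", "g09"))
  got <- classify_duplications(pairs, blocks, outg, pos,
                               td_max_gap = 1, pd_max_gap = 10)
  expect_equal(got$mode, c("WGD", "TD", "PD", "TRD", "DSD"))
  # anchor pairs win even when also rank-adjacent
  adj_block <- data.frame(gene_a = "g01", gene_b = "g02",
                          chr_a = "c1", chr_b = "c1",
                          rank_a = 1, rank_b = 2, block = 1,
                          orientation = "+")
  got2 <- classify_duplications(data.frame(gene_a = "g01", gene_b = "g02"),
                                adj_block, outg[0, ], pos)
  expect_equal(got2$mode, "WGD")
  expect_error(classify_duplications(
    data.frame(gene_a = "g01", gene_b = "h01"), blocks, outg,
    rbind(pos, data.frame(gene = "h01", genome = "H", chrom = "c9",
                          start = 1, end = 10, strand = "+", rank = 1))),
    "two genomes")
})

test_that("removing blocks only moves pairs down the cascade", {
  d <- shared_dup()
  pairs <- d$pairs
  with_blocks <- d$classified
  without <- classify_duplications(pairs, d$blocks[0, ], d$out_blocks,
                                   d$positions)
  prio <- c(WGD = 1, TD = 2, PD = 3, TRD = 4, DSD = 5)
  expect_true(all(prio[without$mode] >= prio[with_blocks$mode]))
  # exhaustiveness and exclusivity
  expect_false(any(is.na(with_blocks$mode)))
  expect_equal(nrow(with_blocks), nrow(pairs))
})

test_that("mode-by-category crosstab reports half-up percent shares", {
  dup <- data.frame(gene_a = c("x1", "x2"), gene_b = c("y1", "y2"),
                    mode = c("WGD", "WGD"))
  genes <- data.frame(gene = c("x1", "x2", "y1", "y2"),
                      og = c("o1", "o2", "o1", "o2"))
  cats <- data.frame(og = c("o1", "o2"),
                     category = c("core", "dispensable"))
  ct <- crosstab_mode_by_category(dup, genes, cats)
  expect_equal(ct$total, 2)
  expect_equal(unname(ct$proportions["WGD"]), 100)
  expect_equal(unname(ct$table["WGD", c("core", "dispensable")]), c(1L, 1L))
})
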