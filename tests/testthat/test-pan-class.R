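test_that("membership matrix counts copies per orthogroup and genome", {
  og <- data.frame(og = c("o1", "o1", "o1", "o2"),
                   genome = c("A", "A", "B", "B"),
                   gene = c("g1", "g2", "g3", "g4"))
  m <- build_membership(og, c("g1", "g2", "g3"))
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(unname(m["o1", ]), c(2L, 1L))
  one <- build_membership(og[4, ], "g4")
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(unname(one[1, 1]), 1L)
  expect_error(build_membership(og, c("g1", "missing")), "missing")
})

test_that("category rule reproduces the printed ranges at n = 22", {
  expect_equal(classify_og(22, 22), "core")
  expect_equal(classify_og(21, 22), "soft-core")
  expect_equal(classify_og(20, 22), "soft-core")
  expect_equal(classify_og(19, 22), "dispensable")
  expect_equal(classify_og(2, 22), "dispensable")
  expect_equal(classify_og(1, 22), "private")
  expect_error(classify_og(0, 22), "range")
  expect_error(classify_og(23, 22), "range")
})

test_that("every orthogroup gets exactly one category, for any genome count", {
  for (n in c(4, 10, 22, 30)) {
    cats <- classify_og(seq_len(n), n)
    expect_true(all(cats %in% c("core", "soft-core", "dispensable",
                                "private")))
    expect_equal(sum(cats == "core"), 1)
    expect_equal(sum(cats == "private"), 1)
    expect_equal(length(cats), n)
    # boundaries: soft-core occupancies form the contiguous run
    # [ceil(0.9 n), n - 1]
    sc <- which(cats == "soft-core")
    if (length(sc) > 0) {
      expect_equal(sc, seq(ceiling(0.9 * n), n - 1))
    }
  }
  expect_warning(classify_og(1, 1), "single-genome")
})

test_that("PAV matrix binarises and can drop core rows", {
  m <- matrix(c(3, 1, 0, 2), 2, 2,
              dimnames = list(c("o1", "o2"), c("A", "B")))
  pav <- pav_matrix(m)
  expect_equal(unname(pav), matrix(c(1L, 1L, 0L, 1L), 2, 2))
  all_core <- matrix(1L, 2, 2, dimnames = list(c("o1", "o2"), c("A", "B")))
  expect_equal(nrow(pav_matrix(all_core, exclude_core = TRUE)), 0)
  b <- shared_bundle()
  st <- shared_stages()
  n_core <- sum(b$truth$categories$category == "core")
  expect_equal(nrow(st$pan$pav), nrow(st$pan$membership) - n_core)
})

test_that("saturation matches exhaustive enumeration on a toy pan-genome", {
  m <- matrix(c(1, 0, 0,
                1, 1, 1,
                0, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("o1", "o2", "o3"), c("A", "B", "C")))
  orders <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  orders <- orders[apply(orders, 1, function(r) length(unique(r)) == 3), ]
  sat <- saturation(m, orders = orders)
  # mean pan at k = 1: genomes hold 2, 2, 1 orthogroups -> 5/3
  expect_equal(sat$pan_mean[1], 5 / 3)
  expect_equal(sat$core_mean[3], 1)
  expect_equal(sat$pan_mean[3], 3)
  expect_equal(sat$pan_sd[3], 0)  # the union is order-free
  expect_equal(sat$pan_mean[1], sat$core_mean[1])
})

test_that("saturation is monotone for every sampled permutation", {
  set.seed(6)
  m <- matrix(rbinom(120, 2, 0.4), 20, 6,
              dimnames = list(sprintf("o%02d", 1:20), sprintf("g%d", 1:6)))
  m <- m[rowSums(m) > 0, ]
  sat <- saturation(m, n_perms = 50, seed = 9)
  pan <- attr(sat, "pan")
  core <- attr(sat, "core")
  expect_true(all(apply(pan, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(core, 1, function(x) all(diff(x) <= 0))))
  sat2 <- saturation(m, n_perms = 50, seed = 9)
  expect_equal(sat$pan_mean, sat2$pan_mean)
})

test_that("per-genome tallies count genes, not orthogroups", {
  m <- matrix(c(2, 1,
                0, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("o1", "o2"), c("A", "B")))
  cats <- data.frame(og = c("o1", "o2"),
                     category = c("core", "private"))
  tal <- per_genome_category_counts(m, cats)
  expect_equal(tal["A", "core"], 2L)
  expect_equal(tal["B", "core"], 1L)
  expect_equal(tal["A", "private"], 0L)
  expect_equal(tal["B", "private"], 3L)
})

test_that("bundle membership and tallies agree with the generator truth", {
  b <- shared_bundle()
  st <- shared_stages()
  m <- st$pan$membership
  occ <- rowSums(m > 0)
  truth <- b$truth$categories
  expect_equal(unname(occ[truth$og]), truth$occupancy)
  # copy counts equal the gene table
  counts <- table(b$genes$og, b$genes$genome)
  expect_equal(unname(m[rownames(counts), colnames(counts)]),
               unname(matrix(as.integer(counts), nrow(counts))))
  tal <- st$pan$per_genome
  for (g in b$genomes) {
    genes_g <- b$genes[b$genes$genome == g, ]
    cat_g <- truth$category[match(genes_g$og, truth$og)]
    expect_equal(unname(tal[g, "core"]), sum(cat_g == "core"))
    expect_equal(unname(tal[g, "dispensable"]), sum(cat_g == "dispensable"))
  }
})
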