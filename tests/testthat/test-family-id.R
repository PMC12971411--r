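test_that("domain-hit filter applies the E-value cutoff with set semantics", {
  hits <- data.frame(gene = c("a", "b", "b", "b", "c"),
                     evalue = c(1e-6, 1e-4, 1e-6, 1e-3, 2e-5))
  expect_equal(filter_domain_hits(hits, 1e-5), c("a", "b"))
  expect_equal(filter_domain_hits(hits[0, ], 1e-5), character())
  expect_error(filter_domain_hits(hits, 0), "cutoff")
})

test_that("malformed domain-hit rows are reported with their line number", {
  path <- tempfile()
  writeLines(c("# comment",
               "g1 - 120 UDPGT PF00201.21 44 1e-30 100 0.1 1 1 1e-30 1e-30 100 0.1 1 44 10 53 10 53 0.95 -",
               "broken row"), path)
  expect_error(read_domtbl(path), "line 3")
  unlink(path)
})

test_that("global identity matches hand-computed values and is symmetric", {
  expect_equal(pairwise_identity("MKVLLD", "MKVLLD"), 100)
  # 8 aligned columns, 6 matches, no gaps
  expect_equal(pairwise_identity("ACDEFGHI", "ACDEFGYV"), 75)
  set.seed(1)
  for (i in 1:5) {
    a <- random_protein(40)
    b <- random_protein(40)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("vectorised identity equals the single-pair computation", {
  set.seed(2)
  ref <- random_protein(60)
  cands <- vapply(1:8, function(i) {
    if (i <= 4) {
      s <- strsplit(ref, "")[[1]]
      idx <- sample(60, sample(0:20, 1))
      s[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       length(idx), replace = TRUE)
      paste(s, collapse = "")
    } else {
      random_protein(sample(40:70, 1))
    }
  }, character(1))
  fast <- panfam:::identity_many(cands, ref)
  slow <- vapply(cands, function(x) pairwise_identity(x, ref), numeric(1))
  expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
})

test_that("identity filter keeps strictly-greater-than-threshold candidates", {
  ref <- c(r1 = "ACDEFGHI")
  cands <- c(keep = "ACDEFGYV",   # 75%
             border = "ACDEWYKV", # 4/8 = 50%, strict > drops it
             drop = "WYWYWYWY")
  expect_equal(pairwise_identity(cands[["border"]], ref[[1]]), 50)
  expect_equal(identity_filter(cands, ref, threshold = 50), "keep")
  expect_error(identity_filter(cands, character(), 50), "reference")
})

test_that("filter composition is order-independent", {
  set.seed(3)
  ref <- c(r = random_protein(50))
  prots <- c(vapply(1:4, function(i) {
    s <- strsplit(ref[[1]], "")[[1]]
    idx <- sample(50, 10)
    s[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10, TRUE)
    paste(s, collapse = "")
  }, character(1)), vapply(1:4, function(i) random_protein(50), character(1)))
  names(prots) <- paste0("p", 1:8)
  hits <- data.frame(gene = names(prots),
                     evalue = rep(c(1e-8, 1e-3), 4))
  a <- identity_filter(prots[filter_domain_hits(hits, 1e-5)], ref, 50)
  passed <- identity_filter(prots, ref, 50)
  b <- intersect(filter_domain_hits(hits, 1e-5), passed)
  expect_setequal(a, b)
})

test_that("PSPG typing finds the consensus and rejects shuffles", {
  model <- read_pspg_model()
  consensus <- panfam:::pspg_consensus()
  expect_equal(nrow(model), nchar(consensus))
  set.seed(4)
  host <- paste0(random_protein(30), consensus, random_protein(20))
  expect_equal(classify_pspg(host, model), "typical")
  expect_warning(out <- classify_pspg(random_protein(10), model), "shorter")
  expect_equal(out, "atypical")
  shuffled <- paste(sample(strsplit(consensus, "")[[1]]), collapse = "")
  # independent per-position score oracle for the shuffled window
  sc <- sum(vapply(seq_len(nrow(model)), function(j) {
    if (grepl(substr(shuffled, j, j), model$residues[j], fixed = TRUE)) {
      model$weight[j]
    } else 0
  }, numeric(1)))
  expect_lt(sc, 0.6 * sum(model$weight))
  expect_equal(classify_pspg(paste0(random_protein(30), shuffled), model),
               "atypical")
})

test_that("PSPG typing on the bundle recovers planted labels exactly", {
  b <- shared_bundle()
  model <- read_pspg_model()
  truth <- merge(b$genes, b$truth$typical, by = "og")
  got <- vapply(b$prot[truth$gene], function(p) classify_pspg(p, model),
                character(1))
  expect_identical(unname(got == "typical"), truth$typical)
})

test_that("group assignment picks the highest-identity reference, ties to the smaller label", {
  set.seed(5)
  base <- random_protein(50)
  mutate <- function(p, k) {
    s <- strsplit(p, "")[[1]]
    idx <- sample(length(s), k)
    s[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k, TRUE)
    paste(s, collapse = "")
  }
  refs <- data.frame(seq = c(mutate(base, 30), mutate(base, 8),
                             mutate(base, 18)),
                     group = c("A", "E", "C"), stringsAsFactors = FALSE)
  ids <- vapply(refs$seq, function(r) pairwise_identity(base, r), numeric(1))
  expect_equal(assign_group(base, refs), refs$group[which.max(ids)])
  expect_equal(assign_group(refs$seq[2], refs), "E")
  tie <- data.frame(seq = c(refs$seq[2], refs$seq[2]),
                    group = c("E", "D"), stringsAsFactors = FALSE)
  expect_equal(assign_group(base, tie), "D")
  many <- assign_groups(c(x = base, y = refs$seq[2]), refs)
  expect_equal(unname(many), c(refs$group[which.max(ids)], "E"))
})

test_that("family naming orders by occupancy, copies, then orthogroup id", {
  m <- matrix(c(1, 1, 1,   # OG_a: occupancy 3
                2, 0, 3,   # OG_b: occupancy 2, 5 copies
                4, 5, 0,   # OG_c: occupancy 2, 9 copies
                0, 4, 5),  # OG_d: occupancy 2, 9 copies
              nrow = 4, byrow = TRUE,
              dimnames = list(c("OG_a", "OG_b", "OG_c", "OG_d"), NULL))
  nm <- name_family_ogs(m, prefix = "FAM")
  expect_equal(nm$og, c("OG_a", "OG_c", "OG_d", "OG_b"))
  expect_equal(nm$family_name, paste0("FAM", 1:4))
  one <- name_family_ogs(m[1, , drop = FALSE])
  expect_equal(one$family_name, "FAM1")
})
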