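# Orthogroup occupancy backbone: membership matrix, the
# core/soft-core/dispensable/private category rule, PAV/CNV matrices,
# per-genome tallies, and pan/core saturation curves.

#' Build the orthogroup x genome membership (copy-count) matrix
#'
#' @param og_long long-format orthogroup table: data frame with columns
#'   `og`, `genome`, `gene` (one row per gene), e.g. from
#'   [read_orthogroups()].
#' @param family_genes character vector of family gene ids; genes outside
#'   this set are excluded. Every family gene must appear in the table.
#' @param genomes optional character vector fixing the column order;
#'   defaults to the sorted genomes present in `og_long`.
#' @return integer matrix, rows = orthogroups, columns = genomes, cell =
#'   family gene copies of that genome in that orthogroup. Rows with zero
#'   total (orthogroups with no family gene) are dropped.
#' @export
build_membership <- function(og_long, family_genes, genomes = NULL) {
  stopifnot(all(c("og", "genome", "gene") %in% names(og_long)))
  missing <- setdiff(family_genes, og_long$gene)
  if (length(missing) > 0) {
    stopf("family gene(s) absent from the orthogroup table: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  if (is.null(genomes)) genomes <- sort(unique(og_long$genome))
  fam <- og_long[og_long$gene %in% family_genes, , drop = FALSE]
  ogs <- sort(unique(fam$og))
  m <- matrix(0L, nrow = length(ogs), ncol = length(genomes),
              dimnames = list(ogs, genomes))
  tab <- table(factor(fam$og, levels = ogs),
               factor(fam$genome, levels = genomes))
  m[] <- as.integer(tab)
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Occupancy-based orthogroup category
#'
#' An orthogroup present in all `n_genomes` genomes is core; in at least
#' ceiling(0.9 n) but not all, soft-core; in exactly one (of several),
#' private; otherwise dispensable. With n = 22 this gives soft-core
#' occupancies 20-21 and dispensable 2-19.
#'
#' @param occupancy integer vector of genome-occupancy counts.
#' @param n_genomes total number of genomes.
#' @return character vector of categories.
#' @examples
#' classify_og(c(22, 20, 19, 1), 22)
#' @export
classify_og <- function(occupancy, n_genomes) {
  if (any(occupancy < 1 | occupancy > n_genomes)) {
    stopf("occupancy out of range [1, %d]", n_genomes)
  }
  if (n_genomes == 1) {
    warnf("single-genome pan-genome: every orthogroup is simultaneously core and private; reporting core")
    return(rep("core", length(occupancy)))
  }
  soft_floor <- ceiling(0.9 * n_genomes)
  ifelse(occupancy == n_genomes, "core",
         ifelse(occupancy == 1, "private",
                ifelse(occupancy >= soft_floor, "soft-core", "dispensable")))
}

#' Orthogroup categories for a membership matrix
#'
#' @param membership matrix from [build_membership()].
#' @return data frame: `og`, `occupancy`, `category`.
#' @export
og_categories <- function(membership) {
  occ <- rowSums(membership > 0)
  data.frame(og = rownames(membership), occupancy = as.integer(occ),
             category = classify_og(occ, ncol(membership)),
             stringsAsFactors = FALSE)
}

#' Presence/absence (PAV) matrix
#'
#' @param membership matrix from [build_membership()].
#' @param exclude_core drop rows classified core (the usual display, since
#'   core rows are all-ones)?
#' @return binary integer matrix.
#' @export
pav_matrix <- function(membership, exclude_core = FALSE) {
  pav <- (membership > 0) + 0L
  if (exclude_core) {
    cat <- og_categories(membership)
    pav <- pav[cat$category != "core", , drop = FALSE]
  }
  pav
}

#' Pan/core saturation curves over random genome orderings
#'
#' For each sampled genome order, pan(k) is the number of orthogroups
#' present in at least one of the first k genomes (cumulative union) and
#' core(k) the number present in all of them (cumulative intersection).
#' Means and standard deviations are taken over orders.
#'
#' @param membership matrix from [build_membership()].
#' @param n_perms number of random genome orders (ignored when `orders`
#'   given).
#' @param seed optional integer seed.
#' @param orders optional matrix of genome orders (one order per row,
#'   entries are column indices), e.g. all permutations for an exact curve.
#' @return object of class `saturation_curve`: data frame with `k`,
#'   `pan_mean`, `pan_sd`, `core_mean`, `core_sd`; per-order trajectories in
#'   attributes `pan` and `core` (order x k matrices), plus `n_perms` and
#'   `seed`.
#' @export
saturation <- function(membership, n_perms = 100, seed = NULL, orders = NULL) {
  pres <- membership > 0
  n <- ncol(pres)
  if (is.null(orders)) {
    if (n_perms < 1) stopf("n_perms must be >= 1")
    orders <- with_seed(seed, {
      t(vapply(seq_len(n_perms), function(i) sample.int(n), integer(n)))
    })
  }
  n_ord <- nrow(orders)
  pan <- matrix(0L, n_ord, n)
  core <- matrix(0L, n_ord, n)
  for (i in seq_len(n_ord)) {
    u <- rep(FALSE, nrow(pres))
    s <- rep(TRUE, nrow(pres))
    for (k in seq_len(n)) {
      col <- pres[, orders[i, k]]
      u <- u | col
      s <- s & col
      pan[i, k] <- sum(u)
      core[i, k] <- sum(s)
    }
  }
  out <- data.frame(k = seq_len(n),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2, stats::sd),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2, stats::sd))
  structure(out, class = c("saturation_curve", "data.frame"),
            pan = pan, core = core, n_perms = n_ord, seed = seed)
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("pan/core saturation over %d genome order(s)%s\n",
              attr(x, "n_perms"),
              if (is.null(attr(x, "seed"))) "" else
                sprintf(" (seed %d)", attr(x, "seed"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-genome gene tallies by orthogroup category
#'
#' Counts genes (copies, not orthogroups) each genome contributes to each
#' category.
#'
#' @param membership matrix from [build_membership()].
#' @param categories optional data frame from [og_categories()]; recomputed
#'   when absent.
#' @return integer matrix, genomes x categories
#'   (core, soft-core, dispensable, private).
#' @export
per_genome_category_counts <- function(membership, categories = NULL) {
  if (is.null(categories)) categories <- og_categories(membership)
  lv <- c("core", "soft-core", "dispensable", "private")
  out <- vapply(lv, function(cat) {
    rows <- categories$og[categories$category == cat]
    colSums(membership[rownames(membership) %in% rows, , drop = FALSE])
  }, numeric(ncol(membership)))
  storage.mode(out) <- "integer"
  out
}
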