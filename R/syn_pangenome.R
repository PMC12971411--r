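# Synthetic pan-genome generator. Produces a fully self-contained bundle —
# per-genome annotations and sequences, orthogroup table, domain-hit and
# similarity tables, labelled references, an outgroup, and (optionally)
# structural variants with expression matrices — whose ground truth
# (occupancy categories, duplication modes, omega values, SV effects) is
# recorded in a truth table so every downstream stage is testable offline.

#' Generator configuration
#'
#' Defaults describe a toy pan-genome of 10 genomes x 3 chromosomes with 36
#' orthogroups (12 core / 4 soft-core / 16 dispensable / 4 private),
#' 120-codon genes, and 13 planted duplication events in the focal (first)
#' genome: 5 WGD pairs forming one collinear block plus 2 each of tandem,
#' proximal, transposed and dispersed events. Omega values are drawn per
#' orthogroup from `omega_grid`.
#'
#' @param n_genomes number of genomes (>= 4).
#' @param n_chromosomes chromosomes per genome (>= 3, so that planted
#'   transposed/dispersed copies land on a chromosome pair that cannot form
#'   a spurious collinear block).
#' @param og_spec data frame with columns `category`, `n`, `copy_min`,
#'   `copy_max`: orthogroup counts per occupancy category and the copy
#'   range used in non-focal genomes.
#' @param dup_spec named integer vector of planted events per mode
#'   (`WGD`, `TD`, `PD`, `TRD`, `DSD`); WGD must be >= 5 to satisfy the
#'   default minimum block size, and TD+PD and TRD+DSD must stay below 5 so
#'   the planted anchors cannot chain into unintended blocks.
#' @param omega_grid dN/dS values sampled per orthogroup.
#' @param n_codons codons per gene (>= 60 to leave room for the 44-codon
#'   PSPG motif).
#' @param ref_branch branch length (neutral substitutions/site) from a
#'   group reference to an orthogroup ancestor.
#' @param gene_branch branch length from an orthogroup ancestor to each
#'   gene copy.
#' @param n_atypical number of dispensable orthogroups whose members lack
#'   the PSPG motif.
#' @param n_decoys non-family decoy genes added to the focal genome (weak
#'   domain hits, unrelated sequence) to exercise the identification
#'   filters.
#' @param sv_spec list for [plant_sv_effects()]: `n_sv`,
#'   `frac_overlapping`, `n_effect`, `effect` (additive TPM shift),
#'   `dp_low_frac` (fraction of depth values below 20), `dispersion`
#'   (negative-binomial), `base_tpm`, `n_background` (non-family genes in
#'   the count matrices), `couple_dosage` (keep the natural gene-count /
#'   dosage coupling, or decouple for null checks).
#' @return object of class `pangenome_config`.
#' @export
pangenome_config <- function(n_genomes = 10,
                             n_chromosomes = 3,
                             og_spec = data.frame(
                               category = c("core", "soft-core",
                                            "dispensable", "private"),
                               n = c(12L, 4L, 16L, 4L),
                               copy_min = c(1L, 1L, 1L, 1L),
                               copy_max = c(1L, 1L, 2L, 1L)),
                             dup_spec = c(WGD = 5L, TD = 2L, PD = 2L,
                                          TRD = 2L, DSD = 2L),
                             omega_grid = c(0.2, 0.5, 1),
                             n_codons = 120,
                             ref_branch = 0.05,
                             gene_branch = 0.06,
                             n_atypical = 3,
                             n_decoys = 3,
                             sv_spec = list()) {
  sv_default <- list(n_sv = 30L, frac_overlapping = 0.5, n_effect = 3L,
                     effect = 300, dp_low_frac = 0.1, dispersion = 0.1,
                     base_tpm = 100, n_background = 150L,
                     couple_dosage = TRUE)
  sv_spec <- utils::modifyList(sv_default, sv_spec)
  cfg <- structure(list(n_genomes = as.integer(n_genomes),
                        n_chromosomes = as.integer(n_chromosomes),
                        og_spec = og_spec, dup_spec = dup_spec,
                        omega_grid = omega_grid, n_codons = as.integer(n_codons),
                        ref_branch = ref_branch, gene_branch = gene_branch,
                        n_atypical = as.integer(n_atypical),
                        n_decoys = as.integer(n_decoys), sv_spec = sv_spec),
                   class = "pangenome_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_genomes < 4) stopf("n_genomes must be >= 4")
  if (cfg$n_chromosomes < 3) stopf("n_chromosomes must be >= 3")
  stopifnot(all(c("category", "n", "copy_min", "copy_max") %in%
                  names(cfg$og_spec)))
  if (any(cfg$og_spec$n < 0) || sum(cfg$og_spec$n) < 1) {
    stopf("og_spec must request a positive number of orthogroups")
  }
  if (any(cfg$og_spec$copy_min < 1 | cfg$og_spec$copy_max < cfg$og_spec$copy_min)) {
    stopf("invalid copy range in og_spec")
  }
  soft_floor <- ceiling(0.9 * cfg$n_genomes)
  if (soft_floor > cfg$n_genomes) {
    stopf("occupancy specification exceeds n_genomes")
  }
  modes <- c("WGD", "TD", "PD", "TRD", "DSD")
  if (!all(modes %in% names(cfg$dup_spec))) {
    stopf("dup_spec must name all of %s", paste(modes, collapse = ", "))
  }
  if (any(cfg$dup_spec < 0)) stopf("dup_spec counts must be >= 0")
  if (cfg$dup_spec[["WGD"]] > 0 && cfg$dup_spec[["WGD"]] < 5) {
    stopf("dup_spec WGD must be 0 or >= 5 (the default minimum block size)")
  }
  if (cfg$dup_spec[["TD"]] + cfg$dup_spec[["PD"]] >= 9 ||
      cfg$dup_spec[["TRD"]] + cfg$dup_spec[["DSD"]] >= 5) {
    stopf("too many planted TD/PD or TRD/DSD events: their anchors could chain into unintended collinear blocks")
  }
  if (any(cfg$omega_grid <= 0)) stopf("omega values must be > 0")
  if (cfg$n_codons < 60) stopf("n_codons must be >= 60")
  if (cfg$sv_spec$effect < 0) stopf("sv effect size must be >= 0")
  if (cfg$sv_spec$n_sv < 1) stopf("sv_spec n_sv must be >= 1")
  invisible(cfg)
}

#' @export
print.pangenome_config <- function(x, ...) {
  cat(sprintf("pan-genome generator config: %d genomes x %d chromosomes, %d orthogroups, %d-codon genes\n",
              x$n_genomes, x$n_chromosomes, sum(x$og_spec$n), x$n_codons))
  cat("  orthogroups:",
      paste(sprintf("%s=%d", x$og_spec$category, x$og_spec$n), collapse = ", "),
      "\n")
  cat("  planted duplications:",
      paste(sprintf("%s=%d", names(x$dup_spec), x$dup_spec), collapse = ", "),
      "\n")
  invisible(x)
}

# 44-residue PSPG consensus used for planted typical members; the shipped
# position-weight model in inst/extdata matches it.
pspg_consensus <- function() {
  "WAPQVEVLAHPAVGCFVTHCGWNSTLESISAGVPMVAWPFFADQ"
}

# Deterministically back-translate a protein using the first codon per
# amino acid in lexicographic order, then let the RNG pick synonyms.
backtranslate <- function(protein) {
  ct <- codon_table()
  vapply(strsplit(protein, "")[[1]], function(aa) {
    opts <- ct$sense[ct$aa[ct$sense] == aa]
    if (length(opts) == 0) stopf("no codon for residue '%s'", aa)
    opts[sample.int(length(opts), 1)]
  }, character(1))
}

#' Generate a synthetic pan-genome bundle
#'
#' @param config from [pangenome_config()].
#' @param seed integer seed; identical config + seed give identical bundles
#'   (and byte-identical files via [write_bundle()]).
#' @return object of class `pangenome_bundle`; see Details.
#' @details The bundle is a list with: `genomes`; `og_info` (orthogroup,
#'   category, occupancy, omega, typical flag, group); `genes` (gene,
#'   genome, og, chrom, start, end, strand); `cds` / `prot` (named
#'   sequence vectors including the outgroup and decoys); `og_long`
#'   (orthogroup table, one row per family gene); `references` (labelled
#'   group references); `domtbl` (domain hits incl. weak decoy hits);
#'   `hits_self` and `hits_outgroup` (similarity tables);
#'   `outgroup_positions`; `sequences` (per-genome chromosome strings);
#'   and `truth` (categories, planted duplication pairs, omega per
#'   orthogroup, typical flags, decoy ids).
#' @export
generate_pangenome <- function(config = pangenome_config(), seed = 1) {
  validate_config(config)
  with_seed(seed, build_pangenome(config, seed))
}

build_pangenome <- function(cfg, seed) {
  n <- cfg$n_genomes
  genomes <- sprintf("G%02d", seq_len(n))
  focal <- genomes[1]
  outg <- "OUT"
  groups <- LETTERS[1:17]
  ct <- codon_table()
  motif_prot <- pspg_consensus()
  motif_len <- nchar(motif_prot)
  motif_at <- cfg$n_codons - motif_len - 10L  # codon index of motif start
  protect <- rep(FALSE, cfg$n_codons)
  protect[motif_at:(motif_at + motif_len - 1)] <- TRUE

  # --- labelled group references (motif embedded) ---
  ref_codons <- lapply(groups, function(g) {
    cod <- random_codons(cfg$n_codons)
    cod[protect] <- backtranslate(motif_prot)
    cod
  })
  names(ref_codons) <- groups
  references <- data.frame(
    name = sprintf("REF_%s", groups), group = groups,
    seq = vapply(ref_codons, function(cc)
      paste(translate_codons(cc), collapse = ""), character(1)),
    stringsAsFactors = FALSE)

  # --- orthogroup roster ---
  spec <- cfg$og_spec
  n_og <- sum(spec$n)
  og_ids <- sprintf("OG%07d", seq_len(n_og))
  category <- rep(spec$category, spec$n)
  copy_min <- rep(spec$copy_min, spec$n)
  copy_max <- rep(spec$copy_max, spec$n)
  soft_floor <- ceiling(0.9 * n)
  occupancy <- integer(n_og)
  members <- vector("list", n_og)
  for (i in seq_len(n_og)) {
    occupancy[i] <- switch(category[i],
      core = n,
      `soft-core` = if (soft_floor > n - 1) n - 1 else
        pick1(soft_floor:(n - 1)),
      dispensable = if (soft_floor - 1 < 2) 2 else
        pick1(2:(soft_floor - 1)),
      private = 1L)
    members[[i]] <- switch(category[i],
      core = genomes,
      private = pick1(genomes),
      # soft-core and dispensable always include the focal genome so that
      # planted events and fillers have material there
      c(focal, sample(genomes[-1], occupancy[i] - 1)))
  }
  omega <- sample(cfg$omega_grid, n_og, replace = TRUE)
  group_of <- sample(groups, n_og, replace = TRUE)
  disp_idx <- which(category == "dispensable")
  typical <- rep(TRUE, n_og)
  if (cfg$n_atypical > 0) {
    typical[sample(disp_idx, min(cfg$n_atypical, length(disp_idx)))] <- FALSE
  }

  # --- orthogroup ancestors ---
  anc <- vector("list", n_og)
  for (i in seq_len(n_og)) {
    cod <- evolve_codons(ref_codons[[group_of[i]]], cfg$ref_branch, omega[i],
                         protect = protect)
    if (!typical[i]) {
      # degrade (not erase) the motif region: enough substitutions to fall
      # far below the PWM cutoff while keeping family-level identity
      hit <- stats::runif(motif_len) < 0.7
      cod[protect][hit] <- random_codons(sum(hit))
    }
    anc[[i]] <- as.character(cod)
  }

  # --- planted duplication events in the focal genome ---
  ds <- cfg$dup_spec
  core_idx <- which(category == "core")
  event_pool <- c(core_idx, which(category == "soft-core"))
  need <- ds[["WGD"]] + ds[["TD"]] + ds[["PD"]] + ds[["TRD"]] + ds[["DSD"]]
  if (length(event_pool) < need) {
    stopf("og_spec provides %d core+soft-core orthogroups but dup_spec plants %d events",
          length(event_pool), need)
  }
  take <- event_pool[seq_len(need)]
  ev <- list()
  k <- 0
  for (m in c("WGD", "TD", "PD", "TRD", "DSD")) {
    ev[[m]] <- take[seq_len(ds[[m]]) + k]
    if (ds[[m]] == 0) ev[[m]] <- integer()
    k <- k + ds[[m]]
  }
  event_idx <- unlist(ev)

  # --- gene roster: copies per genome ---
  gene_rows <- list()
  new_gene <- function(og_i, genome, copy) {
    sprintf("%s_%s_c%d", genome, og_ids[og_i], copy)
  }
  for (i in seq_len(n_og)) {
    for (g in members[[i]]) {
      copies <- if (g == focal) 1L else
        pick1(copy_min[i]:copy_max[i])
      for (cpy in seq_len(copies)) {
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene = new_gene(i, g, cpy), genome = g, og = og_ids[i],
                     og_i = i, stringsAsFactors = FALSE)
      }
    }
  }
  # second focal copies for every planted event
  for (i in event_idx) {
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(gene = new_gene(i, focal, 2L), genome = focal,
                 og = og_ids[i], og_i = i, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)

  # --- gene sequences ---
  cds <- character(nrow(genes))
  names(cds) <- genes$gene
  for (r in seq_len(nrow(genes))) {
    i <- genes$og_i[r]
    cod <- evolve_codons(anc[[i]], cfg$gene_branch, omega[i],
                         protect = if (typical[i]) protect else NULL)
    cds[r] <- paste(cod, collapse = "")
  }
  prot <- vapply(cds, function(s)
    paste(translate_codons(split_codons(s)), collapse = ""), character(1))

  # --- focal genome layout (designed) ---
  fg <- genes$gene[genes$genome == focal]
  first_copy <- function(i) new_gene(i, focal, 1L)
  second_copy <- function(i) new_gene(i, focal, 2L)
  filler_pool <- setdiff(fg, c(vapply(event_idx, first_copy, character(1)),
                               vapply(event_idx, second_copy, character(1))))
  # motif-bearing (typical) fillers first: the outgroup-anchored window must
  # be built from genes that reliably pass the identity filter
  pool_typ <- typical[genes$og_i[match(filler_pool, genes$gene)]]
  filler_pool <- c(filler_pool[pool_typ], filler_pool[!pool_typ])
  fi <- 0
  next_filler <- function() {
    fi <<- fi + 1
    if (fi > length(filler_pool)) {
      stopf("og_spec leaves too few single-copy focal genes to lay out the planted events")
    }
    filler_pool[fi]
  }
  chr1 <- vapply(ev$WGD, first_copy, character(1))
  chr2 <- vapply(ev$WGD, second_copy, character(1))
  odd <- function(v) v[seq_along(v) %% 2 == 1]
  even <- function(v) v[seq_along(v) %% 2 == 0]
  for (i in odd(ev$TD)) chr1 <- c(chr1, next_filler(), first_copy(i), second_copy(i))
  for (i in even(ev$TD)) chr2 <- c(chr2, next_filler(), first_copy(i), second_copy(i))
  for (i in odd(ev$PD)) chr1 <- c(chr1, next_filler(), first_copy(i),
                                  next_filler(), next_filler(), second_copy(i))
  for (i in even(ev$PD)) chr2 <- c(chr2, next_filler(), first_copy(i),
                                   next_filler(), next_filler(), second_copy(i))
  # outgroup-anchored window on chr1: fillers interleaved with TRD sources
  window <- next_filler()
  for (i in ev$TRD) window <- c(window, first_copy(i), next_filler())
  while (length(window) < 5) window <- c(window, next_filler())
  chr1 <- c(chr1, window)
  for (i in ev$DSD) chr1 <- c(chr1, first_copy(i), next_filler())
  chr3 <- character()
  for (i in ev$TRD) chr3 <- c(chr3, second_copy(i), next_filler())
  for (i in ev$DSD) chr3 <- c(chr3, second_copy(i), next_filler())
  # remaining focal genes round-robin over all chromosomes
  rest <- setdiff(filler_pool, filler_pool[seq_len(fi)])
  chroms <- vector("list", cfg$n_chromosomes)
  chroms[[1]] <- chr1
  chroms[[2]] <- chr2
  chroms[[3]] <- chr3
  if (cfg$n_chromosomes > 3) for (j in 4:cfg$n_chromosomes) chroms[[j]] <- character()
  for (j in seq_along(rest)) {
    slot <- ((j - 1) %% cfg$n_chromosomes) + 1
    chroms[[slot]] <- c(chroms[[slot]], rest[j])
  }
  focal_layout <- chroms

  # --- other genomes: random layout ---
  layout <- list()
  layout[[focal]] <- focal_layout
  for (g in genomes[-1]) {
    gg <- sample(genes$gene[genes$genome == g])
    layout[[g]] <- split(gg, rep(seq_len(cfg$n_chromosomes),
                                 length.out = length(gg)))
  }

  # --- decoys (focal genome, non-family) ---
  decoys <- character(cfg$n_decoys)
  if (cfg$n_decoys > 0) {
    decoys <- sprintf("%s_DECOY_%02d", focal, seq_len(cfg$n_decoys))
    for (d in decoys) {
      cod <- random_codons(cfg$n_codons)
      cds[d] <- paste(cod, collapse = "")
      prot[d] <- paste(translate_codons(cod), collapse = "")
    }
    layout[[focal]][[cfg$n_chromosomes]] <-
      c(layout[[focal]][[cfg$n_chromosomes]], decoys)
  }

  # --- outgroup: orthologs of the chr1 window, same order ---
  out_genes <- character(0)
  out_of_og <- character(0)
  window_ogs <- genes$og_i[match(window, genes$gene)]
  for (i in window_ogs) {
    gid <- sprintf("%s_%s_c1", outg, og_ids[i])
    cod <- evolve_codons(anc[[i]], cfg$gene_branch, omega[i],
                         protect = if (typical[i]) protect else NULL)
    cds[gid] <- paste(cod, collapse = "")
    prot[gid] <- paste(translate_codons(split_codons(cds[gid])), collapse = "")
    out_genes <- c(out_genes, gid)
    out_of_og <- c(out_of_og, og_ids[i])
  }

  # --- coordinates and chromosome sequences ---
  gene_len <- cfg$n_codons * 3L
  spacing <- 7000L
  pos_rows <- list()
  sequences <- list()
  place_chrom <- function(gene_ids, genome, chrom) {
    starts <- 3000L + (seq_along(gene_ids) - 1L) * (gene_len + spacing)
    ends <- starts + gene_len - 1L
    strands <- sample(c("+", "-"), length(gene_ids), replace = TRUE)
    chrom_len <- if (length(gene_ids) > 0) max(ends) + 8000L else 10000L
    seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
    for (j in seq_along(gene_ids)) {
      body <- if (strands[j] == "+") cds[[gene_ids[j]]]
              else revcomp(cds[[gene_ids[j]]])
      substr(seq, starts[j], ends[j]) <- body
    }
    list(pos = data.frame(gene = gene_ids, genome = genome, chrom = chrom,
                          start = starts, end = ends, strand = strands,
                          stringsAsFactors = FALSE),
         seq = seq)
  }
  for (g in genomes) {
    sequences[[g]] <- list()
    for (j in seq_len(cfg$n_chromosomes)) {
      chrom <- sprintf("%s_chr%d", g, j)
      pc <- place_chrom(layout[[g]][[j]], g, chrom)
      pos_rows[[chrom]] <- pc$pos
      sequences[[g]][[chrom]] <- pc$seq
    }
  }
  out_chrom <- sprintf("%s_chr1", outg)
  pc <- place_chrom(out_genes, outg, out_chrom)
  outgroup_positions <- pc$pos
  sequences[[outg]] <- stats::setNames(list(pc$seq), out_chrom)
  positions <- do.call(rbind, pos_rows)
  rownames(positions) <- NULL
  decoy_positions <- positions[positions$gene %in% decoys, , drop = FALSE]
  genes <- merge(genes, positions[, c("gene", "chrom", "start", "end", "strand")],
                 by = "gene", sort = TRUE)
  genes <- genes[order(genes$genome, genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  # --- domain-hit table (strong family hits, weak decoy hits) ---
  fam_genes <- genes$gene
  domtbl <- data.frame(
    gene = c(fam_genes, decoys),
    tlen = cfg$n_codons,
    evalue = c(10^-stats::runif(length(fam_genes), 20, 60),
               rep(1e-3, length(decoys))),
    score = c(stats::runif(length(fam_genes), 80, 200),
              rep(12, length(decoys))),
    env_from = motif_at, env_to = motif_at + motif_len - 1,
    stringsAsFactors = FALSE)

  # --- similarity tables (intra-genome and versus outgroup) ---
  synth_hit <- function(a, b) {
    data.frame(query = a, subject = b, identity = 95.0,
               length = cfg$n_codons, mismatch = 6L, gapopen = 0L,
               qstart = 1L, qend = cfg$n_codons, sstart = 1L,
               send = cfg$n_codons, evalue = 1e-180, bitscore = 500,
               stringsAsFactors = FALSE)
  }
  self_rows <- list()
  for (g in genomes) {
    gg <- genes[genes$genome == g, , drop = FALSE]
    for (og in unique(gg$og[duplicated(gg$og)])) {
      ids <- sort(gg$gene[gg$og == og])
      cmb <- utils::combn(ids, 2)
      for (q in seq_len(ncol(cmb))) {
        self_rows[[length(self_rows) + 1L]] <- synth_hit(cmb[1, q], cmb[2, q])
      }
    }
  }
  hits_self <- if (length(self_rows) > 0) do.call(rbind, self_rows)
               else synth_hit("x", "y")[0, , drop = FALSE]
  out_rows <- list()
  for (q in seq_along(out_genes)) {
    mates <- genes$gene[genes$og == out_of_og[q]]
    for (m in sort(mates)) {
      out_rows[[length(out_rows) + 1L]] <- synth_hit(m, out_genes[q])
    }
  }
  hits_outgroup <- do.call(rbind, out_rows)

  # --- truth table ---
  dup_rows <- list()
  for (m in c("WGD", "TD", "PD", "TRD", "DSD")) {
    for (i in ev[[m]]) {
      dup_rows[[length(dup_rows) + 1L]] <-
        data.frame(gene_a = first_copy(i), gene_b = second_copy(i),
                   mode = m, og = og_ids[i], stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    categories = data.frame(og = og_ids, category = category,
                            occupancy = occupancy, stringsAsFactors = FALSE),
    dup_pairs = do.call(rbind, dup_rows),
    omega = data.frame(og = og_ids, omega = omega, stringsAsFactors = FALSE),
    typical = data.frame(og = og_ids, typical = typical,
                         stringsAsFactors = FALSE),
    decoys = decoys)

  og_info <- data.frame(og = og_ids, category = category,
                        occupancy = occupancy, omega = omega,
                        typical = typical, group = group_of,
                        stringsAsFactors = FALSE)
  og_long <- genes[, c("og", "genome", "gene")]
  og_long <- og_long[order(og_long$og, og_long$genome, og_long$gene), ]
  rownames(og_long) <- NULL

  structure(list(config = cfg, seed = seed, genomes = genomes,
                 focal = focal, outgroup_name = outg,
                 og_info = og_info,
                 genes = genes[, c("gene", "genome", "og", "chrom",
                                   "start", "end", "strand")],
                 cds = cds, prot = prot, og_long = og_long,
                 references = references, domtbl = domtbl,
                 hits_self = hits_self, hits_outgroup = hits_outgroup,
                 outgroup_positions = outgroup_positions,
                 decoy_positions = decoy_positions,
                 sequences = sequences, truth = truth,
                 motif_at = motif_at),
            class = "pangenome_bundle")
}

#' @export
print.pangenome_bundle <- function(x, ...) {
  cat(sprintf("synthetic pan-genome bundle (seed %d): %d genomes, %d orthogroups, %d family genes\n",
              x$seed, length(x$genomes), nrow(x$og_info), nrow(x$genes)))
  cat(sprintf("  planted duplication pairs: %d; decoys: %d; outgroup genes: %d\n",
              nrow(x$truth$dup_pairs), length(x$truth$decoys),
              nrow(x$outgroup_positions)))
  if (!is.null(x$sv)) {
    cat(sprintf("  structural variants: %d (%d with planted expression effect)\n",
                nrow(x$sv$variants), nrow(x$truth$sv_effects)))
  }
  invisible(x)
}

#' Plant structural variants and expression matrices on a bundle
#'
#' Places SVs on the focal (reference) genome — a configurable fraction
#' inside gene +/- 2 kb windows, the rest in intergenic space — assigns
#' carrier genomes and per-genome read depths (with a configurable
#' fraction below 20 to exercise the depth filter), and simulates
#' negative-binomial count matrices in which the carriers of an effect-SV
#' have the overlapped orthogroup's expression shifted additively (in TPM
#' units). Samples cover bud and young leaf for every genome plus the
#' remaining tissues and drought/salt young-leaf samples for the focal
#' genome.
#'
#' @param bundle from [generate_pangenome()].
#' @param sv_spec overrides for the bundle config's `sv_spec`.
#' @param seed integer seed.
#' @return the bundle with `sv` (variants/ref/alt/dp/carrier), `expression`
#'   (`counts`, `lengths`, `meta`) and truth entries `sv_effects`,
#'   `bud_enriched`, `stress_induced` added.
#' @export
plant_sv_effects <- function(bundle, sv_spec = NULL, seed = 1) {
  spec <- utils::modifyList(bundle$config$sv_spec, sv_spec %||% list())
  if (spec$effect < 0) stopf("sv effect size must be >= 0")
  with_seed(seed, plant_sv_effects_impl(bundle, spec))
}

plant_sv_effects_impl <- function(bundle, spec) {
  focal <- bundle$focal
  genomes <- bundle$genomes
  n <- length(genomes)
  ref_genes <- bundle$genes[bundle$genes$genome == focal, , drop = FALSE]
  windows <- gene_windows(ref_genes, flank = 2000)

  n_ov <- round(spec$n_sv * spec$frac_overlapping)
  n_sv <- spec$n_sv
  # effect SVs target core orthogroups (present everywhere) so that the
  # association has carriers and non-carriers with expression in all genomes
  core_ogs <- bundle$og_info$og[bundle$og_info$category == "core"]
  core_ref <- ref_genes[ref_genes$og %in% core_ogs, , drop = FALSE]
  core_ref <- core_ref[!duplicated(core_ref$og), , drop = FALSE]
  n_eff <- min(spec$n_effect, n_ov, nrow(core_ref))
  eff_rows <- if (n_eff > 0) core_ref[sample.int(nrow(core_ref), n_eff), ,
                                      drop = FALSE] else core_ref[0, ]
  other_ov <- n_ov - n_eff
  ov_rows <- ref_genes[sample.int(nrow(ref_genes), max(other_ov, 0)), ,
                       drop = FALSE]
  target <- rbind(eff_rows, ov_rows)

  chrom_seq <- function(chrom) {
    bundle$sequences[[focal]][[chrom]]
  }
  mk_sv <- function(i, chrom, pos, effect_gene = NA, effect_og = NA) {
    is_del <- stats::runif(1) < 0.5
    L <- pick1(50:500)
    cs <- chrom_seq(chrom)
    if (is_del) {
      ref <- substr(cs, pos, min(pos + L - 1, nchar(cs)))
      alt <- substr(ref, 1, 1)
    } else {
      ref <- substr(cs, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = ""))
    }
    list(variants = data.frame(chrom = chrom, pos = pos,
                               id = sprintf("SV%04d", i),
                               ref_len = nchar(ref), alt_len = nchar(alt),
                               type = classify_sv_type(nchar(ref), nchar(alt)),
                               stringsAsFactors = FALSE),
         ref = ref, alt = alt,
         effect_gene = effect_gene, effect_og = effect_og)
  }
  svs <- list()
  for (i in seq_len(nrow(target))) {
    w <- windows[windows$gene == target$gene[i], ]
    pos <- pick1(w$window_start:w$window_end)
    svs[[i]] <- mk_sv(i, target$chrom[i], pos,
                      effect_gene = if (i <= n_eff) target$gene[i] else NA,
                      effect_og = if (i <= n_eff) target$og[i] else NA)
  }
  # intergenic SVs in the tail beyond the last window of a random chromosome
  ref_chroms <- unique(ref_genes$chrom)
  for (i in seq_len(n_sv - length(svs))) {
    chrom <- pick1(ref_chroms)
    tail_from <- max(windows$window_end[windows$chrom == chrom]) + 600
    pos <- pick1(tail_from:(tail_from + 2000))
    svs[[length(svs) + 1L]] <- mk_sv(length(svs) + 1L, chrom, pos)
  }
  variants <- do.call(rbind, lapply(svs, `[[`, "variants"))
  carrier <- matrix(FALSE, n_sv, n, dimnames = list(variants$id, genomes))
  dp <- matrix(0L, n_sv, n, dimnames = list(variants$id, genomes))
  for (i in seq_len(n_sv)) {
    k <- pick1(2:max(2, n - 3))
    if (!is.na(svs[[i]]$effect_gene)) k <- max(k, 3)
    carrier[i, sample(genomes[-1], k)] <- TRUE
    low <- stats::runif(n) < spec$dp_low_frac
    dp[i, ] <- ifelse(low, sample(5:19, n, replace = TRUE),
                      sample(25:60, n, replace = TRUE))
  }
  sv <- list(variants = variants,
             ref = vapply(svs, `[[`, "", "ref"),
             alt = vapply(svs, `[[`, "", "alt"),
             dp = dp, carrier = carrier)

  # --- expression: per-gene baselines, planted effects, NB counts ---
  fam <- bundle$genes
  gene_len <- stats::setNames(fam$end - fam$start + 1, fam$gene)
  base <- stats::setNames(stats::rlnorm(nrow(fam), log(spec$base_tpm), 0.4),
                          fam$gene)
  all_ogs <- bundle$og_info$og
  bud_ogs <- sample(all_ogs, 3)
  stress_ogs <- sample(setdiff(core_ogs, bud_ogs), 2)
  if (!spec$couple_dosage) {
    # equalise per-genome family dosage so gene count and total TPM decouple
    cnt <- table(fam$genome)
    scale <- as.numeric(max(cnt) / cnt[fam$genome])
    base <- base * scale
  }
  meta_rows <- list()
  for (g in genomes) {
    for (tis in c("bud", "young_leaf")) {
      meta_rows[[length(meta_rows) + 1L]] <-
        data.frame(sample = sprintf("%s_%s", g, tis), genome = g,
                   tissue = tis, condition = "control", timepoint = 0,
                   stringsAsFactors = FALSE)
    }
  }
  for (tis in c("old_leaf", "flower", "stem", "root")) {
    meta_rows[[length(meta_rows) + 1L]] <-
      data.frame(sample = sprintf("%s_%s", focal, tis), genome = focal,
                 tissue = tis, condition = "control", timepoint = 0,
                 stringsAsFactors = FALSE)
  }
  for (cond in c("drought", "salt")) {
    meta_rows[[length(meta_rows) + 1L]] <-
      data.frame(sample = sprintf("%s_young_leaf_%s_24h", focal, cond),
                 genome = focal, tissue = "young_leaf", condition = cond,
                 timepoint = 24, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_rows)

  # planted effect per (gene, genome): carriers with DP >= 20 of an
  # effect-SV get the additive shift
  eff_tab <- Filter(function(s) !is.na(s$effect_gene), svs)
  effect_of <- matrix(0, nrow(fam), n, dimnames = list(fam$gene, genomes))
  truth_eff <- list()
  for (s in eff_tab) {
    og <- s$effect_og
    carriers <- genomes[carrier[s$variants$id, ] &
                          dp[s$variants$id, ] >= 20]
    rows <- fam$gene[fam$og == og]
    effect_of[rows, carriers] <- effect_of[rows, carriers] + spec$effect
    truth_eff[[length(truth_eff) + 1L]] <-
      data.frame(sv = s$variants$id, gene = s$effect_gene, og = og,
                 effect = spec$effect,
                 carriers = paste(carriers, collapse = ","),
                 stringsAsFactors = FALSE)
  }

  n_bg <- spec$n_background
  bg_names <- as.vector(outer(sprintf("BG%03d", seq_len(n_bg)), genomes,
                              function(b, g) paste(g, b, sep = "_")))
  bg_genome <- rep(genomes, each = n_bg)
  bg_len <- stats::setNames(rep(1000, length(bg_names)), bg_names)
  bg_base <- stats::setNames(stats::rlnorm(length(bg_names), log(50), 0.6),
                             bg_names)
  all_len <- c(gene_len, bg_len)
  counts <- matrix(0, length(all_len), nrow(meta),
                   dimnames = list(names(all_len), meta$sample))
  size <- 1 / spec$dispersion
  for (s in seq_len(nrow(meta))) {
    g <- meta$genome[s]
    tis <- meta$tissue[s]
    cond <- meta$condition[s]
    idx <- fam$genome == g
    mu <- base[fam$gene[idx]] + effect_of[fam$gene[idx], g]
    if (tis == "bud") mu <- mu * ifelse(fam$og[idx] %in% bud_ogs, 5, 1)
    if (cond != "control") mu <- mu * ifelse(fam$og[idx] %in% stress_ogs, 4, 1)
    mu_counts <- mu * (gene_len[fam$gene[idx]] / 1000) * 2
    counts[fam$gene[idx], s] <- stats::rnbinom(sum(idx), mu = mu_counts,
                                               size = size)
    bgi <- bg_genome == g
    counts[bg_names[bgi], s] <- stats::rnbinom(sum(bgi),
                                               mu = bg_base[bg_names[bgi]] * 2,
                                               size = size)
  }

  bundle$sv <- sv
  bundle$expression <- list(counts = counts, lengths = all_len, meta = meta)
  bundle$truth$sv_effects <- if (length(truth_eff) > 0)
    do.call(rbind, truth_eff) else
    data.frame(sv = character(), gene = character(), og = character(),
               effect = numeric(), carriers = character())
  bundle$truth$bud_enriched <- bud_ogs
  bundle$truth$stress_induced <- stress_ogs
  bundle
}

#' Direct simulation harness for the SV-association statistics
#'
#' Draws, per gene, a carrier set over genomes and negative-binomial
#' expression with an additive shift for carriers of effect genes — the
#' same presence/expression process [plant_sv_effects()] plants on a
#' bundle, without the genome-sequence scaffolding. Used to calibrate the
#' association test (type-I error under effect = 0, power under a planted
#' effect).
#'
#' @param n_genes,n_genomes problem size.
#' @param effect_genes indices of genes carrying the effect (default
#'   none).
#' @param effect additive expression shift for carriers.
#' @param dispersion negative-binomial dispersion.
#' @param base baseline expression level.
#' @param seed integer seed.
#' @return list: `presence` (gene x genome 0/1), `expression` (gene x
#'   genome), `effect_genes`.
#' @export
simulate_sv_association <- function(n_genes, n_genomes, effect_genes = integer(),
                                    effect = 0, dispersion = 0.1, base = 100,
                                    seed = 1) {
  with_seed(seed, {
    presence <- matrix(0L, n_genes, n_genomes)
    for (i in seq_len(n_genes)) {
      k <- pick1(3:(n_genomes - 3))
      presence[i, sample.int(n_genomes, k)] <- 1L
    }
    mu <- matrix(base, n_genes, n_genomes)
    mu[effect_genes, ] <- mu[effect_genes, , drop = FALSE] +
      effect * presence[effect_genes, , drop = FALSE]
    expr <- matrix(stats::rnbinom(n_genes * n_genomes, mu = mu,
                                  size = 1 / dispersion),
                   n_genes, n_genomes)
    list(presence = presence, expression = expr, effect_genes = effect_genes)
  })
}

#' Write a bundle to disk in standard formats
#'
#' Per-genome GFF3, CDS/protein FASTA and genome FASTA, an
#' OrthoFinder-style `Orthogroups.tsv`, domain-hit and similarity tables,
#' labelled reference FASTA, outgroup files, truth TSVs, and (if planted)
#' a VCF plus counts/metadata TSVs. Output is byte-identical for identical
#' bundles.
#'
#' @param bundle from [generate_pangenome()] (optionally after
#'   [plant_sv_effects()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  all_pos <- rbind(bundle$genes[, c("gene", "genome", "chrom", "start",
                                    "end", "strand")],
                   bundle$decoy_positions[, c("gene", "genome", "chrom",
                                              "start", "end", "strand")],
                   bundle$outgroup_positions)
  for (g in c(bundle$genomes, bundle$outgroup_name)) {
    pos <- all_pos[all_pos$genome == g, , drop = FALSE]
    pos <- pos[order(pos$chrom, pos$start), , drop = FALSE]
    feats <- list()
    for (r in seq_len(nrow(pos))) {
      gid <- pos$gene[r]
      feats[[length(feats) + 1L]] <- data.frame(
        seqid = pos$chrom[r], source = "panfam",
        type = c("gene", "mRNA", "exon", "CDS"),
        start = pos$start[r], end = pos$end[r], score = ".",
        strand = pos$strand[r], phase = c(".", ".", ".", "0"),
        attributes = c(sprintf("ID=%s", gid),
                       sprintf("ID=%s.t1;Parent=%s", gid, gid),
                       sprintf("ID=%s.t1.e1;Parent=%s.t1", gid, gid),
                       sprintf("ID=%s.t1.c1;Parent=%s.t1", gid, gid)),
        stringsAsFactors = FALSE)
    }
    if (length(feats) > 0) {
      write_gff3(do.call(rbind, feats), p(sprintf("%s.gff3", g)))
    }
    ids <- pos$gene
    write_fasta(bundle$cds[ids], p(sprintf("%s.cds.fa", g)))
    write_fasta(bundle$prot[ids], p(sprintf("%s.prot.fa", g)))
    write_fasta(unlist(bundle$sequences[[g]]), p(sprintf("%s.genome.fa", g)))
  }
  write_orthogroups(bundle$og_long, p("Orthogroups.tsv"),
                    genomes = bundle$genomes)
  write_domtbl(bundle$domtbl, p("domtbl.tsv"))
  write_blast6(bundle$hits_self, p("hits_self.tsv"))
  write_blast6(bundle$hits_outgroup, p("hits_outgroup.tsv"))
  refs <- stats::setNames(bundle$references$seq,
                          sprintf("%s group=%s", bundle$references$name,
                                  bundle$references$group))
  write_fasta(refs, p("references.fa"))
  utils::write.table(bundle$truth$categories, p("truth_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$dup_pairs, p("truth_dup_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$omega, p("truth_omega.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$sv)) {
    write_sv_vcf(bundle$sv, p("svs.vcf"), genomes = bundle$genomes)
    write_counts(bundle$expression$counts, p("counts.tsv"))
    utils::write.table(bundle$expression$meta, p("samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
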