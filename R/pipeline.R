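# Pipeline orchestration: run the stages in dependency order on a
# configuration (or a pre-built bundle) and aggregate a machine-readable
# report mirroring the headline summary tables of a pan-genome
# gene-family study.

default_params <- function() {
  list(evalue = 1e-5, min_identity = 50, pspg_cutoff = 0.6,
       min_block_size = 5, max_gap = 25, td_max_gap = 1, pd_max_gap = 10,
       pair_max_evalue = 1e-10, pair_min_identity = 30,
       flank = 2000, min_dp = 20, alpha = 0.05,
       n_perms = 100, kaks_max_pairs = 10, family_prefix = "FAM")
}

default_stages <- function() {
  list(identify = TRUE, pan = TRUE, dup = TRUE, kaks = TRUE,
       sv = TRUE, expr = TRUE)
}

#' Run the full pan-genome family pipeline
#'
#' Stages run in dependency order: identify -> pan -> dup / kaks / sv /
#' expr. A stage whose toggle is off (or whose prerequisite is off) is
#' skipped and its report section omitted.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   `seed` (integer, drives the generator and saturation permutations),
#'   `simulate` (arguments for [pangenome_config()]; may be empty for
#'   defaults), `stages` (logical toggles, see [default_stages()]),
#'   `params` (stage parameters, see [default_params()]).
#'   Alternatively pass a ready bundle via `bundle`.
#' @param bundle optional pre-built `pangenome_bundle` (overrides the
#'   `simulate` block).
#' @return object of class `panfam_run`: list with `report`
#'   (a `panfam_report`), `stages` (stage artifacts) and `config`.
#' @export
run_pipeline <- function(config = list(), bundle = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stages_on <- utils::modifyList(default_stages(), config$stages %||% list())
  par <- utils::modifyList(default_params(), config$params %||% list())
  if (is.null(bundle)) {
    gen_cfg <- do.call(pangenome_config, config$simulate %||% list())
    bundle <- generate_pangenome(gen_cfg, seed = seed)
    bundle <- plant_sv_effects(bundle, seed = seed + 1L)
  }
  st <- list()

  if (stages_on$identify) {
    st$family <- stage_identify(bundle, par)
  }
  if (stages_on$pan && !is.null(st$family)) {
    st$pan <- stage_pan(bundle, st$family, par, seed)
  }
  if (stages_on$dup && !is.null(st$pan)) {
    st$dup <- stage_dup(bundle, st$family, st$pan, par)
  }
  if (stages_on$kaks && !is.null(st$family)) {
    st$kaks <- stage_kaks(bundle, st$family, par)
  }
  if (stages_on$sv && !is.null(st$pan) && !is.null(bundle$sv)) {
    st$sv <- stage_sv(bundle, st$family, par)
  }
  if (stages_on$expr && !is.null(st$pan) && !is.null(bundle$expression)) {
    st$expr <- stage_expr(bundle, st$pan, par)
  }
  structure(list(report = summarize_stages(st), stages = st,
                 bundle = bundle, config = config),
            class = "panfam_run")
}

stage_identify <- function(bundle, par) {
  by_domain <- filter_domain_hits(bundle$domtbl, cutoff = par$evalue)
  cand <- bundle$prot[by_domain]
  refs <- stats::setNames(bundle$references$seq, bundle$references$name)
  kept <- identity_filter(cand, refs, threshold = par$min_identity)
  model <- read_pspg_model()
  pspg <- vapply(bundle$prot[kept], function(p) {
    classify_pspg(p, model, score_cutoff = par$pspg_cutoff)
  }, character(1))
  groups <- assign_groups(bundle$prot[kept],
                          bundle$references[, c("seq", "group")])
  genes <- bundle$genes[bundle$genes$gene %in% kept, , drop = FALSE]
  genes$pspg_type <- unname(pspg[genes$gene])
  genes$group <- unname(groups[genes$gene])
  list(genes = genes, family_genes = kept, dropped = setdiff(names(bundle$prot), kept))
}

stage_pan <- function(bundle, family, par, seed) {
  membership <- build_membership(bundle$og_long, family$family_genes,
                                 genomes = bundle$genomes)
  categories <- og_categories(membership)
  naming <- name_family_ogs(membership, prefix = par$family_prefix)
  list(membership = membership, categories = categories,
       category_counts = table(factor(categories$category,
                                      c("core", "soft-core", "dispensable",
                                        "private"))),
       pav = pav_matrix(membership, exclude_core = TRUE),
       saturation = saturation(membership, n_perms = par$n_perms,
                               seed = seed),
       per_genome = per_genome_category_counts(membership, categories),
       naming = naming)
}

stage_dup <- function(bundle, family, pan, par) {
  positions <- rank_genes(family$genes)
  pairs <- candidate_pairs_from_hits(bundle$hits_self, positions,
                                     max_evalue = par$pair_max_evalue,
                                     min_identity = par$pair_min_identity)
  anchors <- make_anchors(pairs, positions)
  blocks <- chain_collinear(anchors, min_block_size = par$min_block_size,
                            max_gap = par$max_gap)
  og_pos <- rank_genes(bundle$outgroup_positions)
  og_hits <- bundle$hits_outgroup
  og_hits <- og_hits[og_hits$query %in% positions$gene &
                       og_hits$subject %in% og_pos$gene, , drop = FALSE]
  og_anchors <- make_anchors(
    data.frame(gene_a = og_hits$query, gene_b = og_hits$subject),
    positions, og_pos)
  outgroup_blocks <- chain_collinear(og_anchors,
                                     min_block_size = par$min_block_size,
                                     max_gap = par$max_gap)
  dup_pairs <- classify_duplications(pairs, blocks, outgroup_blocks,
                                     positions,
                                     td_max_gap = par$td_max_gap,
                                     pd_max_gap = par$pd_max_gap)
  crosstab <- crosstab_mode_by_category(dup_pairs, bundle$genes,
                                        pan$categories)
  list(positions = positions, pairs = dup_pairs, blocks = blocks,
       outgroup_blocks = outgroup_blocks, crosstab = crosstab)
}

stage_kaks <- function(bundle, family, par) {
  genes <- family$genes[, c("gene", "genome", "og")]
  est <- og_kaks_distribution(genes, bundle$cds, bundle$prot,
                              max_pairs_per_og = par$kaks_max_pairs)
  tallies <- table(factor(est$class, c("positive", "purifying", "neutral")),
                   useNA = "ifany")
  list(estimates = est, selection_counts = tallies)
}

stage_sv <- function(bundle, family, par) {
  sv <- filter_svs(bundle$sv, min_depth = par$min_dp)
  focal_genes <- family$genes[family$genes$genome == bundle$focal, ,
                              drop = FALSE]
  windows <- gene_windows(focal_genes, flank = par$flank)
  presence <- sv_gene_presence(sv, windows)
  expr <- bundle$expression
  tpm_mat <- suppressWarnings(tpm(expr$counts, expr$lengths))
  fam <- bundle$genes
  res <- list()
  for (tis in c("bud", "young_leaf")) {
    samp <- expr$meta$sample[expr$meta$tissue == tis &
                               expr$meta$condition == "control"]
    gmap <- expr$meta$genome[match(samp, expr$meta$sample)]
    sample_of <- stats::setNames(samp, gmap)
    # per-gene TPM in its own genome's sample, summed to orthogroup x genome
    val <- tpm_mat[cbind(match(fam$gene, rownames(tpm_mat)),
                         match(sample_of[fam$genome], colnames(tpm_mat)))]
    og_tpm <- tapply(val, list(fam$og, fam$genome), sum)
    og_tpm[is.na(og_tpm)] <- 0  # orthogroup absent from a genome: no transcript
    for (i in seq_len(nrow(focal_genes))) {
      g <- focal_genes$gene[i]
      og <- focal_genes$og[i]
      if (!any(presence[g, ])) next
      ex <- og_tpm[og, gmap]
      a <- associate(presence[g, gmap], ex, alpha = par$alpha)
      res[[length(res) + 1L]] <- data.frame(
        gene = g, og = og, tissue = tis, r = a$r, p = a$p, n = a$n,
        significant = a$significant, reason = a$reason,
        stringsAsFactors = FALSE)
    }
  }
  assoc <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(gene = character(), og = character(), tissue = character(),
               r = numeric(), p = numeric(), n = integer(),
               significant = logical(), reason = character())
  list(filtered = sv, windows = windows, presence = presence,
       associations = assoc,
       type_counts = table(factor(sv$variants$type,
                                  c("deletion", "insertion", "other"))))
}

stage_expr <- function(bundle, pan, par) {
  expr <- bundle$expression
  tpm_mat <- suppressWarnings(tpm(expr$counts, expr$lengths))
  fam_genes <- intersect(bundle$genes$gene, rownames(tpm_mat))
  tissue_profile <- profile_expression(tpm_mat, expr$meta, fam_genes,
                                       group = "tissue",
                                       log2_transform = TRUE)
  condition_profile <- profile_expression(
    tpm_mat[, expr$meta$sample[expr$meta$genome == bundle$focal]],
    expr$meta, fam_genes, group = "condition", log2_transform = TRUE)
  dosage <- list()
  for (tis in c("bud", "young_leaf")) {
    samp <- expr$meta[expr$meta$tissue == tis &
                        expr$meta$condition == "control", , drop = FALSE]
    totals <- vapply(seq_len(nrow(samp)), function(s) {
      rows <- intersect(bundle$genes$gene[bundle$genes$genome ==
                                            samp$genome[s]], fam_genes)
      sum(tpm_mat[rows, samp$sample[s]])
    }, numeric(1))
    rec <- dosage_records(pan$membership,
                          stats::setNames(totals, samp$genome))
    dosage[[tis]] <- c(dosage_correlation(rec), list(records = rec))
  }
  list(tpm = tpm_mat, tissue_profile = tissue_profile,
       condition_profile = condition_profile, dosage = dosage)
}

#' Percent shares of a count vector
#'
#' Shares are percentages of the total, rounded half-up to one decimal —
#' the convention used in the report's summary tables.
#'
#' @param counts named non-negative counts.
#' @return list: `counts`, `total`, `shares` (percent).
#' @examples
#' percent_shares(c(WGD = 783, TRD = 656, PD = 513, TD = 236, DSD = 123))
#' @export
percent_shares <- function(counts) {
  counts <- unclass(counts)
  total <- sum(counts)
  if (total == 0) stopf("cannot compute shares of an all-zero count vector")
  list(counts = counts, total = total,
       shares = round_half_up(100 * counts / total, 1))
}

#' Aggregate stage outputs into a report
#'
#' @param stages named list of stage outputs as produced by
#'   [run_pipeline()] (`family`, `pan`, `dup`, `kaks`, `sv`, `expr`); any
#'   subset is accepted, but not an empty one.
#' @return object of class `panfam_report`.
#' @export
summarize_stages <- function(stages) {
  if (length(stages) == 0 || all(vapply(stages, is.null, logical(1)))) {
    stopf("no stage outputs to summarise")
  }
  rep <- list()
  if (!is.null(stages$family)) {
    rep$family_size <- nrow(stages$family$genes)
    rep$pspg_counts <- table(stages$family$genes$pspg_type)
  }
  if (!is.null(stages$pan)) {
    cc <- stages$pan$category_counts
    rep$og_total <- sum(cc)
    rep$categories <- percent_shares(cc)
    sat <- stages$pan$saturation
    rep$saturation <- data.frame(k = sat$k, pan = sat$pan_mean,
                                 core = sat$core_mean)
  }
  if (!is.null(stages$dup)) {
    ct <- stages$dup$crosstab
    rep$duplication <- list(counts = ct$counts, total = ct$total,
                            shares = ct$proportions, crosstab = ct$table)
  }
  if (!is.null(stages$kaks)) {
    rep$selection <- stages$kaks$selection_counts
  }
  if (!is.null(stages$sv)) {
    sig <- stages$sv$associations[stages$sv$associations$significant %in% TRUE, ,
                                  drop = FALSE]
    rep$sv <- list(n_filtered = nrow(stages$sv$filtered$variants),
                   type_counts = stages$sv$type_counts,
                   significant = sig[, c("gene", "og", "tissue", "r", "p")])
  }
  if (!is.null(stages$expr)) {
    rep$dosage <- lapply(stages$expr$dosage, function(d) {
      list(r = d$r, p = d$p, n = d$n)
    })
  }
  structure(rep, class = "panfam_report")
}

#' @export
print.panfam_report <- function(x, ...) {
  cat("== pan-genome family report ==\n")
  if (!is.null(x$family_size)) {
    cat(sprintf("family genes: %d (%s)\n", x$family_size,
                paste(sprintf("%s %d", names(x$pspg_counts), x$pspg_counts),
                      collapse = ", ")))
  }
  if (!is.null(x$og_total)) {
    cat(sprintf("orthogroups: %d\n", x$og_total))
    sh <- x$categories
    for (nm in names(sh$counts)) {
      cat(sprintf("  %-11s %3d (%.1f%%)\n", nm, sh$counts[[nm]],
                  sh$shares[[nm]]))
    }
  }
  if (!is.null(x$duplication)) {
    d <- x$duplication
    cat(sprintf("duplication pairs: %d\n", d$total))
    for (nm in names(d$counts)) {
      cat(sprintf("  %-4s %4d (%.1f%%)\n", nm, d$counts[[nm]],
                  d$shares[[nm]]))
    }
  }
  if (!is.null(x$selection)) {
    cat("selection classes:",
        paste(sprintf("%s %d", names(x$selection), x$selection),
              collapse = ", "), "\n")
  }
  if (!is.null(x$sv)) {
    cat(sprintf("structural variants kept: %d; significant SV-associated gene-tissue pairs: %d\n",
                x$sv$n_filtered, nrow(x$sv$significant)))
  }
  if (!is.null(x$dosage)) {
    for (tis in names(x$dosage)) {
      d <- x$dosage[[tis]]
      cat(sprintf("dosage correlation (%s): r = %.3f, p = %.4g (n = %d)\n",
                  tis, d$r, d$p, d$n))
    }
  }
  if (!is.null(x$saturation)) {
    n <- nrow(x$saturation)
    cat(sprintf("saturation: pan %g -> %g, core %g -> %g over %d genomes\n",
                x$saturation$pan[1], x$saturation$pan[n],
                x$saturation$core[1], x$saturation$core[n], n))
  }
  invisible(x)
}

#' @export
print.panfam_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report a `panfam_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  enc <- rapply(unclass(report), function(v) {
    if (is.table(v)) as.list(v) else v
  }, how = "replace")
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
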