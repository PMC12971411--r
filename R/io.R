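# Readers and writers for the interchange formats the pipeline consumes:
# FASTA (Biostrings), GFF3 (rtracklayer in, deterministic text out),
# OrthoFinder-style Orthogroups.tsv, HMMER domtblout-style tables,
# BLAST outfmt-6-style tables, VCF 4.2 with FORMAT GT:DP (vcfR in),
# counts/metadata/motif TSVs.

#' Read a FASTA file into a named character vector
#'
#' @param path file path.
#' @param type `"dna"` or `"aa"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  ss <- if (type == "dna") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    cat(">", nm, "\n", sep = "", file = con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GFF3 file
#'
#' Thin wrapper over [rtracklayer::readGFF()] returning a plain data frame
#' with 1-based inclusive coordinates.
#'
#' @param path file path.
#' @return data frame with at least `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`.
#' @export
read_gff3 <- function(path) {
  as.data.frame(rtracklayer::readGFF(path))
}

#' Gene coordinate table from a GFF3 data frame
#'
#' @param gff data frame from [read_gff3()].
#' @param feature feature type to extract (default `"gene"`).
#' @return data frame: `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_positions <- function(gff, feature = "gene") {
  g <- gff[gff$type == feature, , drop = FALSE]
  data.frame(gene = as.character(g$ID), chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = as.character(g$strand), stringsAsFactors = FALSE)
}

# Deterministic GFF3 writer for generator output. `features` must carry
# seqid, source, type, start, end, score, strand, phase, attributes.
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   features$seqid, features$source, features$type,
                   features$start, features$end, features$score,
                   features$strand, features$phase, features$attributes)
  writeLines(lines, con)
  invisible(path)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' Expects a header line `Orthogroup<TAB>genome1<TAB>...` and one row per
#' orthogroup with comma-separated gene lists per genome.
#'
#' @param path file path.
#' @return long-format data frame: `og`, `genome`, `gene`.
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  genomes <- names(tab)[-1]
  rows <- list()
  for (g in genomes) {
    genes <- strsplit(tab[[g]], ",[ ]?")
    n <- lengths(genes)
    keep <- n > 0
    rows[[g]] <- data.frame(og = rep(tab[[1]][keep], n[keep]),
                            genome = g, gene = unlist(genes[keep]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$gene != "", , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$og, out$genome, out$gene), , drop = FALSE]
}

#' Write a long-format orthogroup table as Orthogroups.tsv
#'
#' @param og_long data frame with `og`, `genome`, `gene`.
#' @param path file path.
#' @param genomes optional column order; defaults to sorted genomes.
#' @export
write_orthogroups <- function(og_long, path, genomes = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(og_long$genome))
  ogs <- sort(unique(og_long$og))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Orthogroup", genomes), collapse = "\t"), con)
  for (og in ogs) {
    sub <- og_long[og_long$og == og, , drop = FALSE]
    cells <- vapply(genomes, function(g) {
      paste(sort(sub$gene[sub$genome == g]), collapse = ", ")
    }, character(1))
    writeLines(paste(c(og, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a HMMER domtblout-style domain-hit table
#'
#' Whitespace-delimited, `#` comment lines skipped. The standard 23-column
#' layout is assumed: target name (1), query name (4), independent
#' (i-)E-value (13), envelope coordinates (20, 21).
#'
#' @param path file path.
#' @return data frame: `gene`, `domain`, `evalue`, `env_from`, `env_to`.
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  bad <- which(lengths(rows) < 21)
  if (length(bad) > 0) {
    stopf("malformed domain-hit row at line %d of %s", idx[bad[1]], path)
  }
  ev <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 13)))
  from <- suppressWarnings(as.integer(vapply(rows, `[`, "", 20)))
  to <- suppressWarnings(as.integer(vapply(rows, `[`, "", 21)))
  bad <- which(is.na(ev) | is.na(from) | is.na(to))
  if (length(bad) > 0) {
    stopf("malformed domain-hit row at line %d of %s", idx[bad[1]], path)
  }
  data.frame(gene = vapply(rows, `[`, "", 1),
             domain = vapply(rows, `[`, "", 4),
             evalue = ev, env_from = from, env_to = to,
             stringsAsFactors = FALSE)
}

# domtblout-style writer (generator output).
write_domtbl <- function(hits, path, domain = "UDPGT", dom_acc = "PF00201.21",
                         qlen = 44) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target", con)
  lines <- sprintf(paste0("%s - %d %s %s %d %.1e %.1f 0.1 1 1 %.1e %.1e %.1f 0.1 ",
                          "1 %d %d %d %d %d 0.95 -"),
                   hits$gene, hits$tlen, domain, dom_acc, qlen,
                   hits$evalue, hits$score, hits$evalue, hits$evalue,
                   hits$score, qlen, hits$env_from, hits$env_to,
                   hits$env_from, hits$env_to)
  writeLines(lines, con)
  invisible(path)
}

#' Read a BLAST outfmt-6-style similarity table
#'
#' Tab-separated, 12 columns, no header: query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path file path.
#' @return data frame with those columns.
#' @export
read_blast6 <- function(path) {
  cols <- c("query", "subject", "identity", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, col.names = cols)
  tab
}

write_blast6 <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f",
                   hits$query, hits$subject, hits$identity, hits$length,
                   hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                   hits$sstart, hits$send, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Read structural variants from a VCF with FORMAT GT:DP
#'
#' @param path VCF path (plain text or gzipped).
#' @return list with `variants` (data frame: `chrom`, `pos`, `id`,
#'   `ref_len`, `alt_len`, `type`), `dp` (variant x genome integer depth
#'   matrix) and `carrier` (variant x genome logical, TRUE for any
#'   non-reference genotype). Errors if a record lacks DP.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"], ref_len = nchar(ref), alt_len = nchar(alt),
    stringsAsFactors = FALSE)
  variants$type <- classify_sv_type(variants$ref_len, variants$alt_len)
  dp_raw <- vcfR::extract.gt(v, element = "DP")
  if (is.null(dp_raw) || any(is.na(dp_raw))) {
    bad <- if (is.null(dp_raw)) 1L else which(apply(is.na(dp_raw), 1, any))[1]
    stopf("missing DP in VCF record %s at %s:%s", variants$id[bad],
          variants$chrom[bad], variants$pos[bad])
  }
  dp <- matrix(as.integer(dp_raw), nrow = nrow(dp_raw),
               dimnames = dimnames(dp_raw))
  gt <- vcfR::extract.gt(v, element = "GT")
  carrier <- !is.na(gt) & grepl("1", gt)
  rownames(dp) <- rownames(carrier) <- variants$id
  list(variants = variants, dp = dp, carrier = carrier)
}

# Deterministic VCF 4.2 writer (generator output).
write_sv_vcf <- function(sv, path, genomes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  for (chrom in unique(sv$variants$chrom)) {
    writeLines(sprintf("##contig=<ID=%s>", chrom), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genomes), collapse = "\t"), con)
  for (i in seq_len(nrow(sv$variants))) {
    gtdp <- sprintf("%s:%d",
                    ifelse(sv$carrier[i, genomes], "1/1", "0/0"),
                    sv$dp[i, genomes])
    writeLines(paste(c(sv$variants$chrom[i], sv$variants$pos[i],
                       sv$variants$id[i], sv$ref[i], sv$alt[i], ".", "PASS",
                       sprintf("SVTYPE=%s", toupper(substr(sv$variants$type[i], 1, 3))),
                       "GT:DP", gtdp), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cis-element motif table
#'
#' Tab-separated with header columns `name`, `pattern` (IUPAC) and
#' optionally `category`.
#'
#' @param path file path; defaults to the motif table shipped with the
#'   package (common plant promoter elements).
#' @return data frame: `name`, `pattern`, `category`.
#' @export
read_motif_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.tsv", package = "panfam")
  }
  tab <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("name", "pattern") %in% names(tab)))
  if (is.null(tab$category)) tab$category <- NA_character_
  tab
}

#' Read a gene x sample counts matrix (TSV)
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return numeric matrix with gene rownames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
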