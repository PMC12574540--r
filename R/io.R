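# Readers and writers for the standard interchange formats: FASTA, GFF3,
# BLAST outfmt 6, PAV/TSV tables, MCScanX-style collinearity text, plus the
# simulator's file emitter. FASTA goes through Biostrings; GFF3 is
# pre-validated line-wise (so errors carry line numbers) and then parsed
# with rtracklayer.

#' Read protein or nucleotide FASTA as a named character vector
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path file path.
#' @param width line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    lines <- substring(s, seq(1, nchar(s), width), pmin(nchar(s), seq(width, nchar(s) + width - 1, width)))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features; each mRNA becomes one gene model whose
#' `locus_id` is its Parent gene and whose span is the mRNA span (1-based
#' inclusive). CDS length is the summed span of the mRNA's CDS children.
#' Ranks are assigned by (chrom, start) within the genome. mRNAs without a
#' Parent are kept as their own locus with a warning.
#'
#' @param path GFF3 file path.
#' @param genome_id genome label to stamp on the models (default: file name
#'   without extension).
#' @return gene-model data.frame: `gene_id`, `genome_id`, `chrom`, `start`,
#'   `end`, `strand`, `locus_id`, `cds_len`, `rank`.
#' @export
read_gff3 <- function(path, genome_id = sub("\\.gff3?$", "", basename(path))) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    stop_input("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
               body[which(nf != 9L)[1]], nf[which(nf != 9L)[1]])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0L) stop_input("no mRNA features in %s", path)
  parent <- vapply(mrna$Parent, function(p) if (length(p) > 0) p[[1]] else NA_character_,
                   character(1))
  if (anyNA(parent)) {
    warning(sprintf("%d mRNA feature(s) without Parent; kept as own locus", sum(is.na(parent))),
            call. = FALSE)
    parent[is.na(parent)] <- mrna$ID[is.na(parent)]
  }
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_parent <- vapply(cds$Parent, function(p) if (length(p) > 0) p[[1]] else NA_character_,
                       character(1))
  cds_len <- tapply(cds$width, cds_parent, sum)
  out <- data.frame(
    gene_id = mrna$ID,
    genome_id = genome_id,
    chrom = as.character(mrna$seqnames),
    start = mrna$start, end = mrna$end,
    strand = as.character(mrna$strand),
    locus_id = parent,
    cds_len = as.integer(cds_len[mrna$ID]),
    stringsAsFactors = FALSE
  )
  out$cds_len[is.na(out$cds_len)] <- 0L
  assign_ranks(out)
}

#' Write gene models as GFF3
#'
#' Emits one gene feature per locus, one mRNA per gene model and one CDS
#' per mRNA (models are single-exon). Coordinates are written 1-based
#' inclusive.
#'
#' @param genes gene-model data.frame (needs `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `locus_id`).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  loci <- split(seq_len(nrow(g)), g$locus_id)
  loci <- loci[unique(g$locus_id)]
  for (idx in loci) {
    lo <- min(g$start[idx]); hi <- max(g$end[idx])
    locus <- g$locus_id[idx[1]]
    lines <- sprintf("%s\tpangenefam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom[idx[1]], lo, hi, g$strand[idx[1]], locus)
    for (i in idx) {
      lines <- c(lines,
                 sprintf("%s\tpangenefam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i], locus),
                 sprintf("%s\tpangenefam\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                         g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i], g$gene_id[i]))
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read similarity hits in BLAST outfmt 6 layout
#'
#' Twelve tab-separated columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Self hits are dropped;
#' reciprocal duplicates are merged keeping the best bit score (and the
#' smallest E-value). Edges are stored undirected with `gene_a < gene_b`.
#'
#' @param path file path.
#' @return data.frame: `gene_a`, `gene_b`, `bitscore`, `evalue`.
#' @export
read_blast6 <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    stop_input("malformed hit table line %d: expected 12 columns, found %d",
               keep[bad[1]], lengths(fields)[bad[1]])
  }
  if (length(fields) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                   evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]; df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  ord <- order(key, -df$bitscore, df$evalue)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), c("gene_a", "gene_b", "bitscore", "evalue"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write similarity edges in BLAST outfmt 6 layout
#'
#' Placeholder alignment columns (pident/length/coordinates) are filled
#' with nominal values; E-value and bit score are authoritative.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `bitscore`, `evalue`.
#' @param path output path.
#' @export
write_blast6 <- function(edges, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(edges) > 0) {
    writeLines(sprintf("%s\t%s\t90.00\t100\t10\t0\t1\t100\t1\t100\t%s\t%s",
                       edges$gene_a, edges$gene_b,
                       formatC(edges$evalue, format = "e", digits = 2),
                       formatC(edges$bitscore, format = "f", digits = 1)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write a PAV matrix as TSV (OGG rows, genome columns, 0/1)
#' @param pav a [build_pav()] result.
#' @param path output path.
#' @export
write_pav <- function(pav, path) {
  stopifnot(inherits(pav, "pav_matrix"))
  df <- data.frame(ogg_id = rownames(pav$presence), pav$presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a PAV matrix TSV together with a group-label table
#' @param path PAV TSV path (as written by [write_pav()]).
#' @param groups data.frame (`genome_id`, `group`, `group_order`) or path
#'   to a group-label TSV.
#' @return a `pav_matrix`.
#' @export
read_pav <- function(path, groups) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  if (is.character(groups)) {
    groups <- read.table(groups, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  structure(list(presence = m,
                 groups = groups[order(groups$group_order, groups$genome_id), , drop = FALSE],
                 gene_counts = m),
            class = "pav_matrix")
}

# plain deterministic TSV writer (binary mode, fixed na encoding)
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) formatC(col, format = "g", digits = 15) else as.character(col)
    }), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Export synteny blocks as MCScanX-style collinearity text
#'
#' One `## Alignment` header per block followed by numbered anchor lines,
#' for interoperability with collinearity-scan tooling.
#'
#' @param blocks block table from [chain_collinear_blocks()].
#' @param path output path.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("############### Collinearity blocks ###############", con, sep = "\n")
  for (bid in unique(blocks$block_id)) {
    b <- blocks[blocks$block_id == bid, , drop = FALSE]
    plus <- if (b$orientation[1] == "same") "plus" else "minus"
    writeLines(sprintf("## Alignment %s: score=%d e_value=0 N=%d %s&%s %s",
                       sub("^BLK", "", bid), b$score[1], nrow(b),
                       b$chrom_a[1], b$chrom_b[1], plus), con, sep = "\n")
    writeLines(sprintf("%s-%3d:\t%s\t%s\t0", sub("^BLK", "", bid),
                       seq_len(nrow(b)) - 1L, b$gene_a, b$gene_b),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write all simulator outputs to a directory
#'
#' Per genome (and the outgroup): `<id>.protein.faa`, `<id>.cds.fna`,
#' `<id>.gff3`. Plus `edges.blast6`, `anchors.blast6`, `groups.tsv`,
#' `seed_alignment.faa` and the truth tables (`truth_*.tsv`). All files are
#' byte-stable for a fixed configuration.
#'
#' @param sim a `pangenome_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir) {
  stopifnot(inherits(sim, "pangenome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_genome <- split(sim$genes, sim$genes$genome_id)
  per_genome[["OUT"]] <- sim$outgroup_genes
  for (g in names(per_genome)) {
    tab <- per_genome[[g]]
    write_fasta(setNames(tab$protein, tab$gene_id), file.path(dir, paste0(g, ".protein.faa")))
    write_fasta(setNames(tab$cds, tab$gene_id), file.path(dir, paste0(g, ".cds.fna")))
    write_gff3(tab, file.path(dir, paste0(g, ".gff3")))
  }
  write_blast6(sim$edges, file.path(dir, "edges.blast6"))
  if (!is.null(sim$anchor_edges)) {
    write_blast6(sim$anchor_edges, file.path(dir, "anchors.blast6"))
  }
  write_tsv(sim$groups, file.path(dir, "groups.tsv"))
  write_fasta(sim$seed_alignment, file.path(dir, "seed_alignment.faa"))
  write_tsv(sim$ogg_truth, file.path(dir, "truth_oggs.tsv"))
  write_tsv(sim$membership_truth, file.path(dir, "truth_membership.tsv"))
  write_tsv(sim$tandem_truth, file.path(dir, "truth_tandem.tsv"))
  write_tsv(sim$retention_truth, file.path(dir, "truth_retention.tsv"))
  if (!is.null(sim$kaks_truth)) {
    write_tsv(sim$kaks_truth, file.path(dir, "truth_kaks.tsv"))
  }
  invisible(dir)
}
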