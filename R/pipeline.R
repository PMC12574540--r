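# End-to-end pipeline: identify family members -> cluster orthogroups ->
# classify PAV -> tandem arrays -> synteny/retention -> Ka/Ks -> expression.

#' Pipeline configuration
#'
#' Points the pipeline at a directory laid out like [write_pangenome()]
#' output (per-genome `<id>.protein.faa` / `<id>.cds.fna` / `<id>.gff3`,
#' `edges.blast6`, `anchors.blast6`, `groups.tsv`, `seed_alignment.faa`)
#' and records every threshold used downstream.
#'
#' @param dir input directory.
#' @param genome_ids panel genome ids (default: every `<id>.gff3` in `dir`
#'   except the outgroup).
#' @param outgroup_id outgroup genome id (default "OUT"; set `NA` to skip
#'   synteny/Ka/Ks stages).
#' @param wgt_target genome compared against the outgroup (default: first
#'   genome id).
#' @param expression optional path to an expression TSV (genes x samples)
#'   with a sibling `<path>.meta.tsv` sample table.
#' @param rounds,inclusion_threshold,confident_threshold profile-scan
#'   settings (see [iterative_scan()]).
#' @param evalue_cut similarity/anchor E-value cutoff (default 1e-20).
#' @param min_bitscore orthogroup edge bit-score cutoff (default 50).
#' @param max_rank_gap tandem positional cutoff in ranks (default 5).
#' @param u,s collinearity chain gap and minimum block size (defaults 1, 5).
#' @param synteny_u gap allowance used for the outgroup comparison; copy
#'   losses after a genome triplication leave interspersed gaps, so this is
#'   larger by default (20).
#' @param min_delta trend-call threshold in percentage points (default 10).
#' @param out_dir optional directory for result TSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, genome_ids = NULL, outgroup_id = "OUT",
                            wgt_target = NULL, expression = NULL,
                            rounds = 2, inclusion_threshold = 15,
                            confident_threshold = 25,
                            evalue_cut = 1e-20, min_bitscore = 50,
                            max_rank_gap = 5, u = 1, s = 5, synteny_u = 20,
                            min_delta = 10, out_dir = NULL) {
  if (!dir.exists(dir)) stop_config("dir", sprintf("does not exist: %s", dir))
  if (is.null(genome_ids)) {
    genome_ids <- sub("\\.gff3$", "", basename(Sys.glob(file.path(dir, "*.gff3"))))
    genome_ids <- setdiff(genome_ids, outgroup_id)
  }
  if (length(genome_ids) == 0L) stop_config("genome_ids", "no genomes found")
  if (is.null(wgt_target)) wgt_target <- genome_ids[1]
  structure(as.list(environment()), class = "pipeline_config")
}

read_genome_files <- function(dir, id) {
  list(
    proteins = read_fasta(file.path(dir, paste0(id, ".protein.faa")), "AA"),
    cds = read_fasta(file.path(dir, paste0(id, ".cds.fna")), "DNA"),
    genes = read_gff3(file.path(dir, paste0(id, ".gff3")), genome_id = id)
  )
}

#' Run the full pan-gene-family pipeline
#'
#' Stages: profile-based family identification per genome (isoform-filtered
#' loci), orthogroup clustering, PAV classification and group-frequency
#' trends, tandem-array detection, collinearity against the outgroup with
#' copy-retention classes, NG86 Ka/Ks on anchor pairs stratified by copy
#' class, duplication-origin attribution, and (optionally) expression
#' clustering. Returns all stage tables plus a summary; writes TSVs when
#' `config$out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with elements `family`,
#'   `membership`, `pav`, `categories`, `category_summary`, `frequencies`,
#'   `trends`, `arrays`, `blocks`, `retention`, `origin`, `kaks`,
#'   `kaks_strata`, `expression`, `thresholds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  log_msg("config", "E-value cutoff %g, bitscore >= %g, rank gap <= %d, u = %d, s = %d, thresholds %g/%g bits",
          cfg$evalue_cut, cfg$min_bitscore, cfg$max_rank_gap, cfg$u, cfg$s,
          cfg$inclusion_threshold, cfg$confident_threshold)

  ## identify --------------------------------------------------------------
  seed_aln <- read_fasta(file.path(cfg$dir, "seed_alignment.faa"), "AA")
  seed_profile <- build_profile(unname(seed_aln))
  genomes <- lapply(setNames(cfg$genome_ids, cfg$genome_ids),
                    function(id) read_genome_files(cfg$dir, id))
  family <- list()
  all_genes <- list()
  for (id in cfg$genome_ids) {
    gm <- genomes[[id]]
    kept <- filter_isoforms(gm$genes)
    proteome <- gm$proteins[kept$gene_id]
    scan <- iterative_scan(seed_profile, proteome, rounds = cfg$rounds,
                           inclusion_threshold = cfg$inclusion_threshold,
                           confident_threshold = cfg$confident_threshold)
    hits <- scan$hits
    hits$genome_id <- if (nrow(hits) > 0) id else character(0)
    family[[id]] <- hits
    all_genes[[id]] <- kept
    log_msg("identify", "%s: %d family genes of %d loci", id, nrow(hits), nrow(kept))
  }
  family <- do.call(rbind, family)
  rownames(family) <- NULL
  gene_tab <- do.call(rbind, all_genes)
  rownames(gene_tab) <- NULL
  fam_genes <- gene_tab[gene_tab$gene_id %in% family$id, , drop = FALSE]

  ## orthogroups and PAV ----------------------------------------------------
  edges <- read_blast6(file.path(cfg$dir, "edges.blast6"))
  edges <- edges[edges$gene_a %in% fam_genes$gene_id & edges$gene_b %in% fam_genes$gene_id, ,
                 drop = FALSE]
  membership <- cluster_orthogroups(edges, fam_genes$gene_id,
                                    evalue_cut = cfg$evalue_cut,
                                    min_bitscore = cfg$min_bitscore)
  groups <- read.table(file.path(cfg$dir, "groups.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  groups <- groups[groups$genome_id %in% cfg$genome_ids, , drop = FALSE]
  pav <- build_pav(membership, setNames(fam_genes$genome_id, fam_genes$gene_id), groups)
  categories <- classify_oggs(pav)
  category_summary <- summarize_categories(categories, membership)
  freqs <- group_frequencies(pav)
  trends <- detect_monotone_trends(freqs, min_delta = cfg$min_delta)
  log_msg("pangene", "%d OGGs: %s", length(categories),
          paste(sprintf("%d %s", category_summary$n_oggs, category_summary$category),
                collapse = ", "))

  ## tandem arrays ----------------------------------------------------------
  arrays <- detect_tandem_arrays(fam_genes, edges, evalue_cut = cfg$evalue_cut,
                                 max_rank_gap = cfg$max_rank_gap)
  log_msg("tandem", "%d arrays, %d genes",
          length(unique(arrays$array_id)), nrow(arrays))

  ## synteny, retention, Ka/Ks ----------------------------------------------
  blocks <- NULL; retention <- NULL; kaks <- NULL; kaks_strata <- NULL
  if (!is.na(cfg$outgroup_id) &&
      file.exists(file.path(cfg$dir, paste0(cfg$outgroup_id, ".gff3")))) {
    outg <- read_genome_files(cfg$dir, cfg$outgroup_id)
    anchors_path <- file.path(cfg$dir, "anchors.blast6")
    anchors <- if (file.exists(anchors_path)) read_blast6(anchors_path) else
      data.frame(gene_a = character(), gene_b = character(),
                 bitscore = numeric(), evalue = numeric())
    # orient anchors target -> outgroup
    flip <- anchors$gene_a %in% outg$genes$gene_id
    tmp <- anchors$gene_a[flip]
    anchors$gene_a[flip] <- anchors$gene_b[flip]
    anchors$gene_b[flip] <- tmp
    target_genes <- all_genes[[cfg$wgt_target]]
    blocks <- chain_collinear_blocks(anchors, target_genes, outg$genes,
                                     evalue_cut = cfg$evalue_cut,
                                     u = cfg$synteny_u, s = cfg$s)
    retention <- classify_copy_retention(blocks, outg$genes, target_genes)
    log_msg("synteny", "%d blocks; retention classes: %s",
            length(unique(blocks$block_id)),
            paste(names(table(retention)), table(retention), sep = ":", collapse = " "))
    if (nrow(blocks) > 0) {
      target <- genomes[[cfg$wgt_target]]
      pairs <- unique(blocks[, c("gene_a", "gene_b")])
      kaks <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        pa <- target$proteins[[pairs$gene_a[i]]]
        pb <- outg$proteins[[pairs$gene_b[i]]]
        if (nchar(pa) != nchar(pb)) {
          aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(pa),
                                               Biostrings::AAString(pb),
                                               substitutionMatrix = "BLOSUM62",
                                               gapOpening = 10, gapExtension = 0.5)
          pa <- as.character(Biostrings::alignedPattern(aln))
          pb <- as.character(Biostrings::alignedSubject(aln))
        }
        ca <- codon_alignment_from_pair(pa, pb, target$cds[[pairs$gene_a[i]]],
                                        outg$cds[[pairs$gene_b[i]]],
                                        pairs$gene_a[i], pairs$gene_b[i])
        ng86_pair(ca)
      }))
      # stratify by outgroup copy class (gene_b is the outgroup gene)
      strat_in <- kaks
      strat_in$gene_a <- kaks$gene_b
      kaks_strata <- summarize_strata(strat_in, retention)
      log_msg("kaks", "%d pairs, mean ratio %.3f", nrow(kaks),
              mean(kaks$ratio, na.rm = TRUE))
    }
  }

  ## duplication origin -------------------------------------------------------
  origin <- attribute_duplication_origin(gene_tab, arrays, blocks, retention)

  ## expression ---------------------------------------------------------------
  expr <- NULL
  if (!is.null(cfg$expression)) {
    vals <- read.table(cfg$expression, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE)
    meta <- read.table(paste0(cfg$expression, ".meta.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    em <- expression_matrix(as.matrix(vals), meta)
    expr <- cluster_genes(em)
    log_msg("expression", "clustered %d genes over %d samples",
            nrow(em$values), ncol(em$values))
  }

  report <- structure(
    list(family = family, membership = membership, pav = pav,
         categories = categories, category_summary = category_summary,
         frequencies = freqs, trends = trends, arrays = arrays,
         blocks = blocks, retention = retention, origin = origin,
         kaks = kaks, kaks_strata = kaks_strata, expression = expr,
         thresholds = cfg[c("evalue_cut", "min_bitscore", "max_rank_gap", "u", "s",
                            "synteny_u", "inclusion_threshold", "confident_threshold",
                            "min_delta")]),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

codon_alignment_from_pair <- function(pa, pb, cds_a, cds_b, id_a, id_b) {
  back_translate(pa, pb, cds_a, cds_b, id_a = id_a, id_b = id_b)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cs <- x$category_summary
  cat("<pipeline_report>\n")
  cat(sprintf("  family genes: %d in %d OGGs\n", nrow(x$membership),
              length(x$categories)))
  for (i in seq_len(nrow(cs))) {
    cat(sprintf("  %-11s %3d OGGs  %5d genes (%.2f%%)\n", cs$category[i],
                cs$n_oggs[i], cs$n_genes[i], cs$gene_percent[i]))
  }
  cat(sprintf("  tandem arrays: %d (%d genes)\n",
              length(unique(x$arrays$array_id)), nrow(x$arrays)))
  if (!is.null(x$kaks)) {
    cat(sprintf("  Ka/Ks pairs: %d, mean ratio %.3f\n", nrow(x$kaks),
                mean(x$kaks$ratio, na.rm = TRUE)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$family, file.path(out_dir, "family_genes.tsv"))
  write_tsv(report$membership, file.path(out_dir, "ogg_membership.tsv"))
  write_pav(report$pav, file.path(out_dir, "pav_matrix.tsv"))
  write_tsv(data.frame(ogg_id = names(report$categories),
                       category = unname(report$categories),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "ogg_categories.tsv"))
  write_tsv(report$category_summary, file.path(out_dir, "category_summary.tsv"))
  write_tsv(data.frame(ogg_id = rownames(report$frequencies), report$frequencies,
                       check.names = FALSE, stringsAsFactors = FALSE),
            file.path(out_dir, "group_frequencies.tsv"))
  write_tsv(report$arrays, file.path(out_dir, "tandem_arrays.tsv"))
  if (!is.null(report$blocks)) {
    write_tsv(report$blocks, file.path(out_dir, "synteny_blocks.tsv"))
    write_collinearity(report$blocks, file.path(out_dir, "blocks.collinearity"))
    write_tsv(data.frame(gene_id = names(report$retention),
                         copy_count = unname(report$retention),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "copy_retention.tsv"))
  }
  if (!is.null(report$kaks)) {
    write_tsv(report$kaks, file.path(out_dir, "kaks_pairs.tsv"))
    write_tsv(report$kaks_strata, file.path(out_dir, "kaks_strata.tsv"))
  }
  write_tsv(data.frame(gene_id = names(report$origin$origin),
                       origin = unname(report$origin$origin),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "duplication_origin.tsv"))
  write_tsv(report$origin$summary, file.path(out_dir, "duplication_summary.tsv"))
  invisible(out_dir)
}
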