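# Synthetic pangenome with full ground truth.
#
# The generator emulates the study design the toolkit targets: many related
# genomes in ordered domestication groups plus a distant outgroup; a gene
# family whose members share a conserved domain; orthologous gene groups
# with category-structured presence/absence; implanted tandem arrays;
# outgroup genes triplicated in the target genome and partially lost again
# (whole-genome-triplication retention); codon sequences diverged at known
# Ka/Ks targets; and tissue/stage-structured expression. Every downstream
# stage can therefore be scored against exact truth tables.

#' Simulation configuration
#'
#' Defaults mirror the observed structure of a 61-accession tomato panel:
#' four ordered domestication groups of sizes 13/11/12/25, 118 orthologous
#' gene groups mixed 58/31/10/19 over core/softcore/dispensable/private,
#' and purifying-selection Ka/Ks targets below 1.
#'
#' @param n_genomes number of in-panel genomes.
#' @param group_sizes named ordered vector of group sizes (wild to
#'   cultivated); must sum to `n_genomes`.
#' @param n_oggs number of truth orthologous gene groups.
#' @param category_mix named proportions over core, softcore, dispensable,
#'   private; must sum to 1.
#' @param n_chromosomes chromosomes per genome carrying family loci.
#' @param tandem_arrays list of `c(array_size, rank_spacing)` specs; each
#'   spec is implanted once per genome on a distinct core OGG
#'   (`rank_spacing` is the rank difference between consecutive members).
#' @param wgt_fraction proportion of outgroup genes triplicated in the
#'   target genome.
#' @param loss_probs named probabilities of a triplicated gene retaining
#'   3, 2 or 1 copies; must sum to 1.
#' @param target_kaks named per-copy-class Ka/Ks targets (names "1","2","3")
#'   used when diverging retained copies from their outgroup source.
#' @param subs_per_kb substitution density for within-family divergence.
#' @param n_outgroup_genes outgroup genes per outgroup chromosome.
#' @param wgt_targets indices of genomes receiving the triplicated
#'   chromosomes (default 1).
#' @param domain_codons,flank_codons length of the conserved family domain
#'   and of each OGG-specific flank, in codons.
#' @param outgroup_codons CDS length of outgroup genes, in codons.
#' @param kaks_subs substitutions introduced per retained copy (drives the
#'   Ka/Ks signal; default 30).
#' @param isoform_every emit an alternative-splicing isoform every this many
#'   loci (default 20).
#' @param seed integer random seed; all outputs are reproducible from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 61,
                       group_sizes = c(WDR = 13, SP = 11, SLC = 12, SLL = 25),
                       n_oggs = 118,
                       category_mix = c(core = 58, softcore = 31,
                                        dispensable = 10, private = 19) / 118,
                       n_chromosomes = 3,
                       tandem_arrays = list(c(3L, 1L), c(2L, 1L), c(4L, 2L)),
                       wgt_fraction = 0.6,
                       loss_probs = c("3" = 0.2, "2" = 0.3, "1" = 0.5),
                       target_kaks = c("1" = 0.3, "2" = 0.2, "3" = 0.1),
                       subs_per_kb = 20,
                       n_outgroup_genes = 60,
                       wgt_targets = 1L,
                       domain_codons = 60, flank_codons = 20,
                       outgroup_codons = 300, kaks_subs = 30,
                       isoform_every = 20,
                       seed = 1) {
  if (!is_count(n_genomes, 4)) stop_config("n_genomes", "must be a count >= 4")
  if (sum(group_sizes) != n_genomes) stop_config("group_sizes", "must sum to n_genomes")
  if (is.null(names(group_sizes))) stop_config("group_sizes", "must be named (ordered groups)")
  if (!is_count(n_oggs, 1)) stop_config("n_oggs", "must be a count >= 1")
  if (abs(sum(category_mix) - 1) > 1e-9) stop_config("category_mix", "must sum to 1")
  if (!all(c("core", "softcore", "dispensable", "private") %in% names(category_mix))) {
    stop_config("category_mix", "needs core, softcore, dispensable, private")
  }
  if (any(category_mix < 0)) stop_config("category_mix", "must be non-negative")
  if (abs(sum(loss_probs) - 1) > 1e-9) stop_config("loss_probs", "must sum to 1")
  if (!all(c("1", "2", "3") %in% names(loss_probs))) {
    stop_config("loss_probs", 'needs names "1", "2", "3"')
  }
  if (any(target_kaks < 0) || any(target_kaks > 2)) {
    stop_config("target_kaks", "must lie in [0, 2]")
  }
  if (wgt_fraction < 0 || wgt_fraction > 1) stop_config("wgt_fraction", "must be in [0, 1]")
  if (!is_count(seed)) stop_config("seed", "must be an integer")
  structure(as.list(environment()), class = "sim_config")
}

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds), no.init.codon = TRUE))
}

translate_many <- function(cds_vec) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds_vec),
                                     no.init.codon = TRUE))
}

#' Evolve a coding sequence at a target Ka/Ks
#'
#' Introduces `n_subs` single-nucleotide substitutions, choosing each to be
#' synonymous with probability `q = S / (S + target_kaks * N)` (S, N the
#' Nei-Gojobori site counts of the input), so that the expected NG86 ratio
#' of the (input, output) pair approaches `target_kaks`. Substitutions are
#' drawn uniformly over the single-nucleotide codon neighbors of the chosen
#' class; stop codons are never created.
#'
#' @param cds coding sequence (length divisible by 3, no internal stop; a
#'   terminal stop codon is left untouched).
#' @param target_kaks desired Ka/Ks (>= 0).
#' @param n_subs number of substitutions.
#' @param seed optional seed for a private RNG stream; `NULL` uses the
#'   current stream.
#' @return mutated coding sequence (same length).
#' @export
evolve_codons <- function(cds, target_kaks, n_subs, seed = NULL) {
  run <- function() {
    codons <- split_codons(cds)
    n <- length(codons)
    has_stop <- codons %in% STOP_CODONS
    mutable <- which(!has_stop)
    if (any(has_stop[-n])) stop_input("internal stop codon at codon %d", which(has_stop)[1])
    if (target_kaks < 0) stop_config("target_kaks", "must be >= 0")
    if (n_subs == 0) return(cds)
    S <- sum(.syn_sites_table[codons[mutable]])
    N <- 3 * length(mutable) - S
    q <- S / (S + target_kaks * N)
    for (k in seq_len(n_subs)) {
      want_syn <- runif(1) < q
      for (try in 1:100) {
        i <- sample(mutable, 1)
        nb <- .codon_neighbors[[codons[i]]]
        pool <- if (want_syn) nb$syn else nb$non
        if (length(pool) > 0) {
          codons[i] <- pool[sample.int(length(pool), 1)]
          break
        }
      }
    }
    paste(codons, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# largest-remainder apportionment of n items to proportions p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  setNames(as.integer(k), names(p))
}

#' Simulate a ground-truthed pangenome
#'
#' See [sim_config()] for the study-design knobs. Optionally writes all
#' per-genome FASTA/GFF3 files and truth tables to `out_dir` (see
#' [write_pangenome()]).
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return object of class `pangenome_sim`: list with `genes` (gene-model
#'   table over all panel genomes incl. triplicated chromosomes),
#'   `outgroup_genes`, `edges` (family similarity edges), `anchor_edges`
#'   (target-outgroup anchors), `ogg_truth` (per OGG: category, subfamily,
#'   presence count), `membership_truth` (gene -> truth OGG),
#'   `tandem_truth`, `retention_truth`, `kaks_truth`, `groups`,
#'   `seed_alignment`, `references`, `config`.
#' @export
simulate_pangenome <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- with_seed(config$seed, simulate_pangenome_impl(config))
  if (!is.null(out_dir)) write_pangenome(sim, out_dir)
  sim
}

simulate_pangenome_impl <- function(cfg) {
  N <- cfg$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(N))
  groups <- data.frame(
    genome_id = genome_ids,
    group = rep(names(cfg$group_sizes), cfg$group_sizes),
    group_order = rep(seq_along(cfg$group_sizes), cfg$group_sizes),
    stringsAsFactors = FALSE
  )

  ## --- truth OGG categories and presence sets -------------------------
  cat_counts <- apportion(cfg$n_oggs, cfg$category_mix[c("core", "softcore", "dispensable", "private")])
  if (cat_counts[["dispensable"]] > 0 && N < 4) {
    stop_config("n_genomes", "must be >= 4 to host dispensable OGGs")
  }
  category <- rep(names(cat_counts), cat_counts)
  ogg_ids <- sprintf("T%04d", seq_len(cfg$n_oggs))
  presence <- lapply(seq_len(cfg$n_oggs), function(i) {
    switch(category[i],
           core = genome_ids,
           softcore = genome_ids[-sample.int(N, 1)],
           dispensable = sort(sample(genome_ids, sample(2:(N - 2), 1))),
           private = sample(genome_ids, 1))
  })
  names(presence) <- ogg_ids

  ## --- family sequences ----------------------------------------------
  subfam_labels <- sprintf("UGT%d", 71:91)  # 21 reference subfamilies
  subfamily <- subfam_labels[(seq_len(cfg$n_oggs) - 1L) %% length(subfam_labels) + 1L]
  domain_cds <- random_cds(cfg$domain_codons)
  dlen <- cfg$domain_codons * 3
  ogg_cds <- lapply(seq_len(cfg$n_oggs), function(i) {
    dom <- evolve_codons(domain_cds, 1, round(0.10 * dlen))
    paste0(random_cds(cfg$flank_codons), dom, random_cds(cfg$flank_codons))
  })
  names(ogg_cds) <- ogg_ids
  ogg_domain_prot <- vapply(ogg_cds, function(x) {
    translate_cds(substr(x, cfg$flank_codons * 3 + 1, cfg$flank_codons * 3 + dlen))
  }, character(1))
  seed_alignment <- ogg_domain_prot[seq_len(min(10, cfg$n_oggs))]
  references <- setNames(
    vapply(ogg_cds[!duplicated(subfamily)], translate_cds, character(1)),
    subfamily[!duplicated(subfamily)]
  )

  ## --- per-genome gene tables -----------------------------------------
  gene_len_nt <- nchar(ogg_cds[[1]])
  fam_subs <- max(1L, round(cfg$subs_per_kb * gene_len_nt / 1000))
  home_chrom <- sprintf("chr%02d", (seq_len(cfg$n_oggs) - 1L) %% cfg$n_chromosomes + 1L)
  core_ids <- ogg_ids[category == "core"]

  all_rows <- list()
  tandem_truth <- list()
  edge_rows <- list()
  ogg_first_gene <- setNames(rep(NA_character_, cfg$n_oggs), ogg_ids)

  for (g in genome_ids) {
    loci <- list()     # each: list(ogg, cds, tandem_spec)
    # tandem specs for this genome: one core OGG per spec, all distinct
    td_oggs <- if (length(cfg$tandem_arrays) > 0) {
      sample(core_ids, length(cfg$tandem_arrays))
    } else character(0)
    rows <- list()
    locus_no <- 0L
    iso_counter <- 0L
    for (ch in sprintf("chr%02d", seq_len(cfg$n_chromosomes))) {
      pos <- 1L
      rank_guess <- 0L
      slots <- ogg_ids[home_chrom == ch]
      slots <- slots[vapply(slots, function(o) g %in% presence[[o]], logical(1))]
      emit_bg <- function(k) {
        for (b in seq_len(k)) {
          locus_no <<- locus_no + 1L
          len <- 3L * sample(80:120, 1)
          cds <- random_cds(len / 3L)
          gid <- sprintf("%s_loc%05d.1", g, locus_no)
          rows[[length(rows) + 1L]] <<- data.frame(
            gene_id = gid, genome_id = g, chrom = ch,
            start = pos, end = pos + len - 1L,
            strand = sample(c("+", "-"), 1),
            locus_id = sprintf("%s_loc%05d", g, locus_no),
            ogg = NA_character_, subfamily = NA_character_,
            is_family = FALSE, region = NA_character_,
            cds = cds, protein = NA_character_,
            stringsAsFactors = FALSE)
          pos <<- pos + len + 200L + rgeom(1, 1 / 300)
        }
      }
      emit_family <- function(ogg, array_member = FALSE) {
        locus_no <<- locus_no + 1L
        iso_counter <<- iso_counter + 1L
        cds <- evolve_codons(ogg_cds[[ogg]], 1, fam_subs)
        len <- nchar(cds)
        locus <- sprintf("%s_loc%05d", g, locus_no)
        gid <- paste0(locus, ".1")
        strand <- sample(c("+", "-"), 1)
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_id = gid, genome_id = g, chrom = ch,
          start = pos, end = pos + len - 1L, strand = strand,
          locus_id = locus, ogg = ogg, subfamily = subfamily[match(ogg, ogg_ids)],
          is_family = TRUE, region = NA_character_,
          cds = cds, protein = NA_character_,
          stringsAsFactors = FALSE)
        if (iso_counter %% cfg$isoform_every == 0L) {
          short <- substr(cds, 1, 3L * floor(nchar(cds) / 4.5))
          rows[[length(rows) + 1L]] <<- data.frame(
            gene_id = paste0(locus, ".2"), genome_id = g, chrom = ch,
            start = pos, end = pos + nchar(short) - 1L, strand = strand,
            locus_id = locus, ogg = ogg, subfamily = subfamily[match(ogg, ogg_ids)],
            is_family = TRUE, region = NA_character_,
            cds = short, protein = NA_character_,
            stringsAsFactors = FALSE)
        }
        pos <<- pos + len + 200L + rgeom(1, 1 / 300)
        gid
      }
      for (ogg in slots) {
        emit_bg(1L + rgeom(1, 0.5))
        spec_idx <- match(ogg, td_oggs)
        if (!is.na(spec_idx)) {
          spec <- cfg$tandem_arrays[[spec_idx]]
          size <- spec[1]; spacing <- spec[2]
          members <- character(size)
          for (m in seq_len(size)) {
            if (m > 1L && spacing > 1L) emit_bg(spacing - 1L)
            members[m] <- emit_family(ogg)
          }
          tandem_truth[[length(tandem_truth) + 1L]] <- data.frame(
            genome_id = g, chrom = ch, gene_id = members,
            truth_array = sprintf("%s_%s", g, ogg), stringsAsFactors = FALSE)
          # within-genome similarity among array members
          prs <- t(combn(members, 2))
          edge_rows[[length(edge_rows) + 1L]] <- data.frame(
            gene_a = prs[, 1], gene_b = prs[, 2],
            bitscore = 350, evalue = 1e-50, stringsAsFactors = FALSE)
        } else {
          emit_family(ogg)
        }
      }
      emit_bg(1L + rgeom(1, 0.5))
    }
    all_rows[[g]] <- do.call(rbind, rows)
  }
  genes <- do.call(rbind, all_rows)
  rownames(genes) <- NULL

  ## --- family similarity edges (star per OGG + weak inter-OGG noise) ---
  primary <- genes[genes$is_family & endsWith(genes$gene_id, ".1"), , drop = FALSE]
  for (ogg in ogg_ids) {
    members <- primary$gene_id[primary$ogg == ogg]
    members <- sort(members)
    ogg_first_gene[ogg] <- members[1]
    if (length(members) > 1L) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        gene_a = members[1], gene_b = members[-1],
        bitscore = 300, evalue = 1e-80, stringsAsFactors = FALSE)
    }
  }
  # weak cross-OGG hits that must be filtered out by the E-value cutoff
  n_noise <- min(200L, nrow(primary))
  if (n_noise >= 2L) {
    a <- sample(primary$gene_id, n_noise)
    b <- sample(primary$gene_id, n_noise)
    ok <- primary$ogg[match(a, primary$gene_id)] != primary$ogg[match(b, primary$gene_id)]
    if (any(ok)) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        gene_a = a[ok], gene_b = b[ok], bitscore = 45, evalue = 1e-5,
        stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edge_rows)
  # canonical undirected storage
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]; edges$gene_a[swap] <- edges$gene_b[swap]; edges$gene_b[swap] <- tmp
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), , drop = FALSE]
  rownames(edges) <- NULL

  ## --- outgroup and whole-genome-triplication chromosomes --------------
  n_out <- cfg$n_outgroup_genes
  out_ids <- sprintf("OUT_g%04d", seq_len(n_out))
  out_cds <- vapply(seq_len(n_out), function(i) random_cds(cfg$outgroup_codons), character(1))
  out_pos <- cumsum(rep(cfg$outgroup_codons * 3 + 500L, n_out)) - (cfg$outgroup_codons * 3 + 500L) + 1L
  outgroup_genes <- data.frame(
    gene_id = out_ids, genome_id = "OUT", chrom = "chrV01",
    start = out_pos, end = out_pos + cfg$outgroup_codons * 3L - 1L,
    strand = "+", locus_id = sub("\\.1$", "", out_ids),
    ogg = NA_character_, subfamily = NA_character_,
    is_family = FALSE, region = NA_character_,
    cds = out_cds, protein = translate_many(out_cds),
    stringsAsFactors = FALSE
  )

  n_trip <- round(cfg$wgt_fraction * n_out)
  triplicated <- sort(sample.int(n_out, n_trip))
  copy_class <- rep(1L, n_out)
  copy_class[triplicated] <- sample(c(3L, 2L, 1L), n_trip, replace = TRUE,
                                    prob = cfg$loss_probs[c("3", "2", "1")])
  regions_of <- lapply(seq_len(n_out), function(i) {
    if (i %in% triplicated) sort(sample.int(3, copy_class[i])) else 1L
  })

  anchor_rows <- list()
  kaks_rows <- list()
  wgt_rows <- list()
  for (tg in cfg$wgt_targets) {
    g <- genome_ids[tg]
    for (r in 1:3) {
      pos <- 1L
      for (i in seq_len(n_out)) {
        if (!(r %in% regions_of[[i]])) next
        cls <- as.character(copy_class[i])
        target <- cfg$target_kaks[[cls]]
        cds <- evolve_codons(out_cds[i], target, cfg$kaks_subs)
        gid <- sprintf("%s_W%d_%04d.1", g, r, i)
        len <- nchar(cds)
        wgt_rows[[length(wgt_rows) + 1L]] <- data.frame(
          gene_id = gid, genome_id = g, chrom = sprintf("chrW%02d", r),
          start = pos, end = pos + len - 1L, strand = "+",
          locus_id = sub("\\.1$", "", gid),
          ogg = NA_character_, subfamily = NA_character_,
          is_family = FALSE, region = sprintf("W%d", r),
          cds = cds, protein = NA_character_,
          stringsAsFactors = FALSE)
        pos <- pos + len + 500L
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          gene_a = gid, gene_b = out_ids[i], bitscore = 500, evalue = 1e-60,
          stringsAsFactors = FALSE)
        kaks_rows[[length(kaks_rows) + 1L]] <- data.frame(
          gene_a = out_ids[i], gene_b = gid, genome = g,
          copy_class = copy_class[i], target = target,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(wgt_rows) > 0) genes <- rbind(genes, do.call(rbind, wgt_rows))
  genes$protein <- translate_many(genes$cds)
  genes <- assign_ranks(genes)
  anchor_edges <- if (length(anchor_rows) > 0) do.call(rbind, anchor_rows) else NULL
  kaks_truth <- if (length(kaks_rows) > 0) do.call(rbind, kaks_rows) else NULL

  ogg_truth <- data.frame(
    ogg = ogg_ids, category = category,
    subfamily = subfamily,
    n_genomes = lengths(presence),
    stringsAsFactors = FALSE
  )
  membership <- primary[, c("gene_id", "ogg")]
  names(membership) <- c("gene_id", "truth_ogg")
  tandem_truth <- if (length(tandem_truth) > 0) do.call(rbind, tandem_truth) else
    data.frame(genome_id = character(), chrom = character(),
               gene_id = character(), truth_array = character())
  retention_truth <- data.frame(
    gene_id = out_ids,
    triplicated = seq_len(n_out) %in% triplicated,
    copy_count = copy_class,
    stringsAsFactors = FALSE
  )
  structure(
    list(genes = genes, outgroup_genes = outgroup_genes,
         edges = edges, anchor_edges = anchor_edges,
         ogg_truth = ogg_truth, membership_truth = membership,
         presence_truth = presence,
         tandem_truth = tandem_truth, retention_truth = retention_truth,
         kaks_truth = kaks_truth, groups = groups,
         seed_alignment = seed_alignment, references = references,
         config = cfg),
    class = "pangenome_sim"
  )
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat(sprintf("<pangenome_sim> %d genomes, %d truth OGGs, %d genes (+%d outgroup), seed %d\n",
              x$config$n_genomes, nrow(x$ogg_truth), nrow(x$genes),
              nrow(x$outgroup_genes), x$config$seed))
  invisible(x)
}

#' Simulate a tissue/stage expression matrix with archetype truth
#'
#' Each gene is assigned one expression archetype: `ubiquitous` (shared
#' high baseline profile), `tissue_specific` (high in one assigned tissue),
#' `stage_ramp` (expression increasing with stage), or `silent` (all zero).
#' Values follow the archetype template times multiplicative log-normal
#' noise. For recovery tests the truth label of a gene is
#' `archetype[:tissue]`, since two tissue-specific genes with different
#' target tissues have genuinely different profiles.
#'
#' @param genes character vector of gene ids (or a `pangenome_sim`, from
#'   which the first genome's family genes are taken).
#' @param tissues character vector of tissue labels (>= 2).
#' @param stages character vector of stage labels.
#' @param replicates biological replicates per condition (default 3).
#' @param noise_sd log2-scale noise standard deviation (default 0.2).
#' @param mix archetype proportions (named, sums to 1).
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame: gene_id, archetype, tissue, label).
#' @export
simulate_expression <- function(genes,
                                tissues = c("root", "stem", "leaf", "bud", "flower", "fruit"),
                                stages = sprintf("S%02d", 1:11),
                                replicates = 3, noise_sd = 0.2,
                                mix = c(ubiquitous = 0.3, tissue_specific = 0.4,
                                        stage_ramp = 0.2, silent = 0.1),
                                seed = 1) {
  if (length(tissues) < 2L) stop_config("tissues", "needs >= 2 tissue labels")
  if (length(stages) < 1L) stop_config("stages", "needs >= 1 stage label")
  if (inherits(genes, "pangenome_sim")) {
    g1 <- genes$genes
    g1 <- g1[g1$is_family & g1$genome_id == g1$genome_id[1] & endsWith(g1$gene_id, ".1"), ]
    genes <- g1$gene_id
  }
  if (length(genes) < 2L) stop_input("need >= 2 genes")
  with_seed(seed, {
    n <- length(genes)
    counts <- apportion(n, mix)
    archetype <- sample(rep(names(counts), counts))
    assigned_tissue <- ifelse(archetype == "tissue_specific",
                              sample(tissues, n, replace = TRUE), NA)
    meta <- expand.grid(replicate = seq_len(replicates), stage = stages,
                        tissue = tissues, stringsAsFactors = FALSE)
    meta <- meta[, c("tissue", "stage", "replicate")]
    meta$sample_id <- sprintf("%s.%s.r%d", meta$tissue, meta$stage, meta$replicate)
    # fixed per-condition baseline shared by the ubiquitous archetype: high
    # everywhere with mild, non-monotone condition-to-condition structure,
    # so it resembles a housekeeping profile rather than any tissue spike
    cond_idx <- as.integer(factor(paste(meta$tissue, meta$stage),
                                  levels = unique(paste(meta$tissue, meta$stage))))
    ubiq_shape <- 2^(5.5 + 0.8 * sin(cond_idx * 2.4))
    stage_idx <- match(meta$stage, stages)
    template <- function(i) {
      switch(archetype[i],
             ubiquitous = ubiq_shape,
             tissue_specific = ifelse(meta$tissue == assigned_tissue[i], 200, 2),
             stage_ramp = 2^(1 + 6 * (stage_idx - 1) / max(1, length(stages) - 1)),
             silent = rep(0, nrow(meta)))
    }
    values <- t(vapply(seq_len(n), function(i) {
      base <- template(i)
      base * 2^rnorm(nrow(meta), 0, noise_sd)
    }, numeric(nrow(meta))))
    dimnames(values) <- list(genes, meta$sample_id)
    truth <- data.frame(
      gene_id = genes, archetype = archetype, tissue = assigned_tissue,
      label = ifelse(is.na(assigned_tissue), archetype,
                     paste(archetype, assigned_tissue, sep = ":")),
      stringsAsFactors = FALSE
    )
    list(matrix = expression_matrix(values, meta), truth = truth)
  })
}
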