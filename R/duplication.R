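# Gene duplication analysis: tandem arrays from positional clustering of
# similar genes, collinear block chaining between genomes, and
# whole-genome-triplication copy retention scored against an outgroup.

#' Recompute chromosome ranks of a gene table
#'
#' Rank is the 0-based index of a gene after sorting by (chrom, start)
#' within its genome; it is the coordinate the tandem and synteny operations
#' work in.
#'
#' @param genes gene-model data.frame (see [read_gff3()]) with at least
#'   `gene_id`, `genome_id`, `chrom`, `start`.
#' @return the same data.frame with column `rank` rewritten, sorted by
#'   (genome, chrom, start).
#' @export
assign_ranks <- function(genes) {
  genes <- genes[order(genes$genome_id, genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  key <- paste(genes$genome_id, genes$chrom, sep = "\r")
  genes$rank <- unlist(lapply(split(seq_along(key), key)[unique(key)],
                              function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(genes) <- NULL
  genes
}

#' Collapse alternative isoforms to one gene model per locus
#'
#' Keeps, per `locus_id`, the model with the longest CDS (ties broken by the
#' smallest `gene_id`) and recomputes ranks. Models without a `locus_id` are
#' treated as their own locus with a warning.
#'
#' @param genes gene-model data.frame with `locus_id` and `cds_len` (or
#'   `cds` sequences, from which lengths are taken).
#' @return filtered gene-model data.frame with ranks recomputed.
#' @export
filter_isoforms <- function(genes) {
  if (is.null(genes$cds_len)) {
    genes$cds_len <- nchar(genes$cds)
  }
  if (anyNA(genes$locus_id) || any(!nzchar(genes$locus_id))) {
    warning("gene model(s) without locus_id treated as their own locus", call. = FALSE)
    orphan <- is.na(genes$locus_id) | !nzchar(genes$locus_id)
    genes$locus_id[orphan] <- paste0("orphan:", genes$gene_id[orphan])
  }
  ord <- order(genes$genome_id, genes$locus_id, -genes$cds_len, genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  keep <- !duplicated(paste(g$genome_id, g$locus_id, sep = "\r"))
  assign_ranks(g[keep, , drop = FALSE])
}

#' Detect tandem gene arrays
#'
#' Restricts similarity edges to pairs on the same chromosome of one genome
#' passing the E-value cutoff, then single-linkage clusters genes on
#' positional distance: two similar genes join when their rank distance
#' (default) or base-pair distance is at most the cutoff, and clusters are
#' the transitive closure of joined pairs. Clusters of two or more genes
#' are reported as arrays, members ordered by rank, with ids
#' `<genome>_TA<k>` numbered along the genome.
#'
#' @param genes isoform-filtered gene-model data.frame (one genome or many;
#'   arrays never span genomes).
#' @param edges similarity edges (`gene_a`, `gene_b`, `evalue`).
#' @param evalue_cut maximum E-value (default 1e-20; must be > 0).
#' @param max_rank_gap positional cutoff in ranks (default 5).
#' @param distance `"rank"` (default) or `"bp"` (midpoint distance, cutoff
#'   `max_bp_gap`).
#' @param max_bp_gap positional cutoff in bp when `distance = "bp"`
#'   (default 100000).
#' @return data.frame with one row per array member: `array_id`,
#'   `genome_id`, `chrom`, `gene_id`, `rank`.
#' @export
detect_tandem_arrays <- function(genes, edges, evalue_cut = 1e-20,
                                 max_rank_gap = 5, distance = c("rank", "bp"),
                                 max_bp_gap = 1e5) {
  distance <- match.arg(distance)
  if (evalue_cut <= 0) stop_config("evalue_cut", "must be > 0")
  genes <- assign_ranks(genes)
  info <- genes[, c("gene_id", "genome_id", "chrom", "start", "end", "rank")]
  rownames(info) <- info$gene_id
  e <- edges[edges$evalue <= evalue_cut, , drop = FALSE]
  e <- e[e$gene_a %in% info$gene_id & e$gene_b %in% info$gene_id, , drop = FALSE]
  same <- info[e$gene_a, "genome_id"] == info[e$gene_b, "genome_id"] &
    info[e$gene_a, "chrom"] == info[e$gene_b, "chrom"]
  e <- e[same, , drop = FALSE]
  if (nrow(e) > 0) {
    pos_dist <- if (distance == "rank") {
      abs(info[e$gene_a, "rank"] - info[e$gene_b, "rank"])
    } else {
      abs((info[e$gene_a, "start"] + info[e$gene_a, "end"]) / 2 -
            (info[e$gene_b, "start"] + info[e$gene_b, "end"]) / 2)
    }
    cutoff <- if (distance == "rank") max_rank_gap else max_bp_gap
    e <- e[pos_dist <= cutoff, , drop = FALSE]
  }
  if (nrow(e) == 0L) {
    return(data.frame(array_id = character(), genome_id = character(),
                      chrom = character(), gene_id = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_edgelist(cbind(e$gene_a, e$gene_b), directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- Filter(function(m) length(m) >= 2L, clusters)
  rows <- lapply(clusters, function(m) {
    sub <- info[m, , drop = FALSE]
    sub[order(sub$rank), c("gene_id", "genome_id", "chrom", "rank"), drop = FALSE]
  })
  # deterministic array numbering: by genome, chromosome, first member rank
  first <- t(vapply(rows, function(r)
    c(r$genome_id[1], r$chrom[1], sprintf("%09d", r$rank[1])), character(3)))
  rows <- rows[order(first[, 1], first[, 2], first[, 3])]
  per_genome <- ave(seq_along(rows), vapply(rows, function(r) r$genome_id[1], character(1)),
                    FUN = seq_along)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(array_id = sprintf("%s_TA%04d", r$genome_id[1], per_genome[i]),
               genome_id = r$genome_id, chrom = r$chrom,
               gene_id = r$gene_id, rank = r$rank, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# anchor-index coordinates: order the family genes of each chromosome by
# rank and number them 1..k; chain gap constraints are expressed in this
# coordinate, i.e. "skip at most u intervening family genes"
anchor_index <- function(genes) {
  genes <- assign_ranks(genes)
  key <- paste(genes$genome_id, genes$chrom, sep = "\r")
  idx <- unlist(lapply(split(seq_along(key), key)[unique(key)],
                       function(i) seq_along(i)), use.names = FALSE)
  setNames(idx, genes$gene_id)
}

# longest chain under the gap rule among anchors with coordinates (x, y);
# direction +1 (same) or -1 (inverted) for y. Returns indices of the chain.
chain_dp <- function(x, y, u, dir) {
  n <- length(x)
  ord <- order(x, dir * y)
  x <- x[ord]; y <- y[ord]
  best_len <- integer(n); pred <- integer(n)
  for (i in seq_len(n)) {
    best_len[i] <- 1L; pred[i] <- 0L
    for (j in seq_len(i - 1L)) {
      dx <- x[i] - x[j]
      dy <- dir * (y[i] - y[j])
      if (dx >= 1L && dx <= u + 1L && dy >= 1L && dy <= u + 1L) {
        if (best_len[j] + 1L > best_len[i] ||
            (best_len[j] + 1L == best_len[i] && (pred[i] == 0L || j < pred[i]))) {
          best_len[i] <- best_len[j] + 1L
          pred[i] <- j
        }
      }
    }
  }
  end <- which(best_len == max(best_len))[1]
  chain <- integer(0)
  while (end != 0L) {
    chain <- c(end, chain)
    end <- pred[end]
  }
  ord[chain]
}

#' Chain collinear anchor pairs into synteny blocks
#'
#' Works per chromosome pair and orientation in anchor-index coordinates
#' (each chromosome's family genes numbered consecutively by rank).
#' Consecutive chain members may skip at most `u` intervening family genes
#' on either genome (index gap at most `u + 1`). Maximal chains are
#' extracted greedily, longest first (ties by smallest starting anchor),
#' each anchor used once; chains shorter than `s` anchors are discarded.
#' Defaults follow common collinearity-scan practice: `e = 1e-20`, `u = 1`,
#' `s = 5`.
#'
#' @param anchor_pairs similarity edges between the two genomes (`gene_a` in
#'   genome A, `gene_b` in genome B, `evalue`).
#' @param genes_a,genes_b gene-model data.frames of the two genomes.
#' @param evalue_cut anchor E-value cutoff (default 1e-20).
#' @param u maximum skipped family genes between consecutive anchors
#'   (default 1; >= 0).
#' @param s minimum anchors per block (default 5; >= 2).
#' @return data.frame with one row per anchor: `block_id`, `genome_a`,
#'   `genome_b`, `chrom_a`, `chrom_b`, `gene_a`, `gene_b`, `orientation`,
#'   `score` (anchor count of the block).
#' @export
chain_collinear_blocks <- function(anchor_pairs, genes_a, genes_b,
                                   evalue_cut = 1e-20, u = 1, s = 5) {
  if (u < 0) stop_config("u", "must be >= 0")
  if (s < 2) stop_config("s", "must be >= 2")
  empty <- data.frame(block_id = character(), genome_a = character(),
                      genome_b = character(), chrom_a = character(),
                      chrom_b = character(), gene_a = character(),
                      gene_b = character(), orientation = character(),
                      score = integer(), stringsAsFactors = FALSE)
  idx_a <- anchor_index(genes_a)
  idx_b <- anchor_index(genes_b)
  chrom_a <- setNames(genes_a$chrom, genes_a$gene_id)
  chrom_b <- setNames(genes_b$chrom, genes_b$gene_id)
  ap <- anchor_pairs[anchor_pairs$evalue <= evalue_cut, , drop = FALSE]
  ap <- ap[ap$gene_a %in% names(idx_a) & ap$gene_b %in% names(idx_b), , drop = FALSE]
  if (nrow(ap) == 0L) return(empty)
  ap$chrom_a <- unname(chrom_a[ap$gene_a])
  ap$chrom_b <- unname(chrom_b[ap$gene_b])
  ap$x <- unname(idx_a[ap$gene_a])
  ap$y <- unname(idx_b[ap$gene_b])
  blocks <- list()
  for (cp in split(ap, paste(ap$chrom_a, ap$chrom_b, sep = "\r"))) {
    pool <- cp
    repeat {
      if (nrow(pool) == 0L) break
      ch_same <- chain_dp(pool$x, pool$y, u, dir = +1L)
      ch_inv <- chain_dp(pool$x, pool$y, u, dir = -1L)
      use_same <- length(ch_same) >= length(ch_inv)
      ch <- if (use_same) ch_same else ch_inv
      if (length(ch) < s) break
      rows <- pool[ch, , drop = FALSE]
      rows <- rows[order(rows$x), , drop = FALSE]
      rows$orientation <- if (use_same) "same" else "inverted"
      rows$score <- length(ch)
      blocks[[length(blocks) + 1L]] <- rows
      pool <- pool[-ch, , drop = FALSE]
    }
  }
  if (length(blocks) == 0L) return(empty)
  # deterministic block order: score desc, then chromosomes, then start
  keys <- t(vapply(blocks, function(b)
    c(sprintf("%09d", 1e9 - b$score[1]), b$chrom_a[1], b$chrom_b[1],
      sprintf("%09d", min(b$x))), character(4)))
  blocks <- blocks[order(keys[, 1], keys[, 2], keys[, 3], keys[, 4])]
  out <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = sprintf("BLK%04d", i),
               genome_a = genes_a$genome_id[1], genome_b = genes_b$genome_id[1],
               chrom_a = b$chrom_a, chrom_b = b$chrom_b,
               gene_a = b$gene_a, gene_b = b$gene_b,
               orientation = b$orientation, score = b$score,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Copy-retention class of outgroup genes from synteny blocks
#'
#' For each outgroup gene, the copy count is the number of distinct
#' target-genome block regions in which it appears as an anchor. Block
#' regions are distinct (target chromosome, block) pairs, except that blocks
#' overlapping on one target chromosome are merged and counted once (guards
#' against fragmented chains double-counting one region). Genes in no block
#' score 0; counts of 3 or more are capped at 3.
#'
#' @param blocks block table from [chain_collinear_blocks()] with the
#'   outgroup as genome B (`gene_b` outgroup gene ids).
#' @param outgroup_genes outgroup gene-model data.frame (defines the full
#'   gene universe; genes without anchors get 0).
#' @param genes_a target-genome gene-model data.frame (for block spans).
#' @return named integer vector: copy count in 0..3 per outgroup gene.
#' @export
classify_copy_retention <- function(blocks, outgroup_genes, genes_a) {
  counts <- setNames(integer(nrow(outgroup_genes)), outgroup_genes$gene_id)
  if (nrow(blocks) == 0L) return(counts)
  genes_a <- assign_ranks(genes_a)
  rank_a <- setNames(genes_a$rank, genes_a$gene_id)
  spans <- do.call(rbind, lapply(split(blocks, blocks$block_id), function(b) {
    r <- rank_a[b$gene_a]
    data.frame(block_id = b$block_id[1], chrom_a = b$chrom_a[1],
               lo = min(r), hi = max(r), stringsAsFactors = FALSE)
  }))
  # merge overlapping blocks on one target chromosome into regions
  spans <- spans[order(spans$chrom_a, spans$lo, spans$hi), , drop = FALSE]
  region_id <- character(nrow(spans))
  cur_chrom <- ""; cur_hi <- -Inf; cur_region <- 0L
  for (i in seq_len(nrow(spans))) {
    if (spans$chrom_a[i] != cur_chrom || spans$lo[i] > cur_hi) {
      cur_region <- cur_region + 1L
      cur_chrom <- spans$chrom_a[i]
      cur_hi <- spans$hi[i]
    } else {
      cur_hi <- max(cur_hi, spans$hi[i])
    }
    region_id[i] <- sprintf("R%05d", cur_region)
  }
  names(region_id) <- spans$block_id
  per_gene <- tapply(region_id[blocks$block_id], blocks$gene_b,
                     function(r) length(unique(r)))
  hit <- intersect(names(per_gene), names(counts))
  counts[hit] <- pmin(3L, as.integer(per_gene[hit]))
  counts
}

#' Attribute a duplication origin to each gene
#'
#' `TD` for members of a tandem array, `WGT` for anchors of a synteny block
#' whose outgroup partner retains two or more copies, `both` when both
#' apply, `none` otherwise. Per-group and per-subfamily percentage summaries
#' use two-decimal half-up rounding.
#'
#' @param genes gene-model data.frame (gene universe).
#' @param arrays tandem-array table from [detect_tandem_arrays()].
#' @param blocks block table from [chain_collinear_blocks()] (target genome
#'   as genome A), or `NULL`.
#' @param retention copy counts from [classify_copy_retention()], or `NULL`.
#' @return list with `origin` (named character vector per gene) and
#'   `summary` (data.frame: label, n, percent).
#' @export
attribute_duplication_origin <- function(genes, arrays, blocks = NULL, retention = NULL) {
  unknown <- setdiff(arrays$gene_id, genes$gene_id)
  if (length(unknown) > 0L) {
    stop_input("array member absent from gene set: %s", unknown[1])
  }
  origin <- setNames(rep("none", nrow(genes)), genes$gene_id)
  td <- genes$gene_id %in% arrays$gene_id
  wgt_genes <- character(0)
  if (!is.null(blocks) && nrow(blocks) > 0 && !is.null(retention)) {
    dup_out <- names(retention)[retention >= 2]
    wgt_genes <- unique(blocks$gene_a[blocks$gene_b %in% dup_out])
  }
  wgt <- genes$gene_id %in% wgt_genes
  origin[td & !wgt] <- "TD"
  origin[!td & wgt] <- "WGT"
  origin[td & wgt] <- "both"
  tab <- table(factor(origin, levels = c("TD", "WGT", "both", "none")))
  summary <- data.frame(
    label = names(tab), n = as.integer(tab),
    percent = gene_share_percent(as.integer(tab), length(origin)),
    stringsAsFactors = FALSE
  )
  list(origin = origin, summary = summary)
}
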