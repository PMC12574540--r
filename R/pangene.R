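# Orthologous gene group (OGG) clustering, presence/absence classification
# and domestication-trajectory frequency trends.

#' Cluster genes into orthologous gene groups
#'
#' Single-linkage graph clustering: genes are nodes, similarity edges that
#' pass both the E-value and bit-score cutoffs connect them, and each
#' connected component is one OGG. Genes without any passing edge form
#' singleton OGGs. OGG ids are assigned as `OG%07d` in order of decreasing
#' member count, ties broken by the smallest member gene id, mirroring
#' OrthoFinder-style labels.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `bitscore`,
#'   `evalue` (undirected; see [read_blast6()]).
#' @param genes character vector of all gene ids to cluster (singletons
#'   included).
#' @param evalue_cut maximum E-value for an edge (default 1e-20).
#' @param min_bitscore minimum bit score for an edge (default 0).
#' @return data.frame with columns `gene_id`, `ogg_id`.
#' @export
cluster_orthogroups <- function(edges, genes, evalue_cut = 1e-20, min_bitscore = 0) {
  genes <- sort(unique(genes))
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes)
    if (length(unknown) > 0L) {
      stop_input("edge references unknown gene id: %s", unknown[1])
    }
    keep <- edges$evalue <= evalue_cut & edges$bitscore >= min_bitscore
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$gene_a, edges$gene_b))
  }
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  sizes <- lengths(members)
  first_id <- vapply(members, function(m) min(m), character(1))
  ord <- order(-sizes, first_id)
  members <- members[ord]
  ogg_ids <- sprintf("OG%07d", seq_along(members) - 1L)
  out <- data.frame(
    gene_id = unlist(members, use.names = FALSE),
    ogg_id = rep(ogg_ids, lengths(members)),
    stringsAsFactors = FALSE
  )
  out[order(out$ogg_id, out$gene_id), , drop = FALSE]
}

#' Build a presence/absence (PAV) matrix from OGG membership
#'
#' @param membership data.frame with `gene_id`, `ogg_id`.
#' @param gene_genomes named character vector: genome id per gene id.
#' @param groups data.frame with columns `genome_id`, `group`, `group_order`
#'   covering every genome.
#' @return object of class `pav_matrix`: list with `presence` (binary OGG x
#'   genome matrix), `groups` (data.frame ordered by `group_order`), and
#'   `gene_counts` (OGG x genome copy-number matrix).
#' @export
build_pav <- function(membership, gene_genomes, groups) {
  genome <- unname(gene_genomes[membership$gene_id])
  if (anyNA(genome)) {
    stop_input("gene id without genome assignment: %s",
               membership$gene_id[which(is.na(genome))[1]])
  }
  missing_grp <- setdiff(unique(genome), groups$genome_id)
  if (length(missing_grp) > 0L) {
    stop_input("genome without group label: %s", missing_grp[1])
  }
  counts <- table(membership$ogg_id, factor(genome, levels = sort(groups$genome_id)))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), colnames(counts)))
  presence <- (counts > 0) * 1L
  structure(
    list(presence = presence,
         groups = groups[order(groups$group_order, groups$genome_id), , drop = FALSE],
         gene_counts = counts),
    class = "pav_matrix"
  )
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("<pav_matrix> %d OGGs x %d genomes (%d groups)\n",
              nrow(x$presence), ncol(x$presence), length(unique(x$groups$group))))
  invisible(x)
}

#' Classify OGGs as core / softcore / dispensable / private
#'
#' With N genomes: present in all N genomes -> core; in exactly N - 1 ->
#' softcore; in 2 to N - 2 -> dispensable; in exactly 1 -> private. The
#' partition is total and exclusive.
#'
#' @param pav a [build_pav()] result (or a binary OGG x genome matrix).
#' @return named character vector: category per OGG id.
#' @export
classify_oggs <- function(pav) {
  m <- if (inherits(pav, "pav_matrix")) pav$presence else pav
  n <- ncol(m)
  if (n < 2L) stop_input("classification undefined for fewer than 2 genomes")
  counts <- rowSums(m)
  if (any(counts == 0)) stop_input("PAV matrix contains an all-zero OGG row")
  cat_of <- function(k) {
    if (k == n) "core"
    else if (k == 1L) "private"
    else if (k == n - 1L) "softcore"
    else "dispensable"
  }
  setNames(vapply(counts, cat_of, character(1)), rownames(m))
}

#' Per-group OGG presence frequencies
#'
#' Percentage of genomes in each population group that carry the OGG,
#' rounded half-up to integer percent (the convention used for trajectories
#' such as 62%, 91%, 92%, 100%).
#'
#' @param pav a [build_pav()] result.
#' @return matrix OGG x group (in group order) of integer percentages.
#' @export
group_frequencies <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  grp <- pav$groups
  group_levels <- unique(grp$group[order(grp$group_order)])
  out <- sapply(group_levels, function(g) {
    ids <- grp$genome_id[grp$group == g]
    if (length(ids) == 0L) stop_config("groups", sprintf("group %s is empty", g))
    round_half_up(100 * rowSums(pav$presence[, ids, drop = FALSE]) / length(ids))
  })
  out <- matrix(out, nrow = nrow(pav$presence),
                dimnames = list(rownames(pav$presence), group_levels))
  out
}

#' Detect monotone presence-frequency trends across ordered groups
#'
#' An OGG is `rising` when its group-frequency trajectory is non-decreasing
#' along the group order, not constant, and spans at least `min_delta`
#' percentage points in total; `falling` is symmetric. All other OGGs are
#' unlabeled.
#'
#' @param freqs OGG x group matrix from [group_frequencies()].
#' @param group_order character vector of group labels, wild to cultivated.
#' @param min_delta minimum total change in percentage points (default 10).
#' @return list with character vectors `rising` and `falling` (OGG ids).
#' @export
detect_monotone_trends <- function(freqs, group_order = colnames(freqs), min_delta = 10) {
  if (length(group_order) < 3L) stop_input("need >= 3 ordered groups for a trend")
  unknown <- setdiff(group_order, colnames(freqs))
  if (length(unknown) > 0L) stop_input("unknown group in order: %s", unknown[1])
  f <- freqs[, group_order, drop = FALSE]
  d <- f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  total <- f[, ncol(f)] - f[, 1]
  rising <- rownames(f)[apply(d >= 0, 1, all) & total >= min_delta]
  falling <- rownames(f)[apply(d <= 0, 1, all) & total <= -min_delta]
  list(rising = rising, falling = falling)
}

#' Category count and gene share summary of a classified pangenome
#'
#' @param categories named vector from [classify_oggs()].
#' @param membership OGG membership data.frame (`gene_id`, `ogg_id`).
#' @return data.frame per category: `n_oggs`, `n_genes`, `gene_percent`
#'   (two decimals, half-up), in the order core, softcore, dispensable,
#'   private.
#' @export
summarize_categories <- function(categories, membership) {
  levels <- c("core", "softcore", "dispensable", "private")
  genes_per_ogg <- table(membership$ogg_id)
  total_genes <- nrow(membership)
  rows <- lapply(levels, function(cat) {
    oggs <- names(categories)[categories == cat]
    n_genes <- sum(genes_per_ogg[names(genes_per_ogg) %in% oggs])
    data.frame(category = cat, n_oggs = length(oggs), n_genes = n_genes,
               gene_percent = gene_share_percent(n_genes, total_genes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an OrthoFinder-style Orthogroups.tsv table (adapter)
#'
#' First column is the orthogroup id; remaining columns are per-genome,
#' comma-separated gene lists. Returns the same membership layout as
#' [cluster_orthogroups()].
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `ogg_id`.
#' @export
read_orthogroups <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    genes <- unlist(strsplit(unlist(tab[i, -1]), ",[ ]*"))
    genes <- genes[nzchar(genes) & !is.na(genes)]
    if (length(genes) == 0L) return(NULL)
    data.frame(gene_id = genes, ogg_id = tab[i, 1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
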