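# Distance-based phylogenetics: p-distances, canonical neighbor-joining
# with deterministic tie-breaking, and subfamily clade summaries. Trees are
# ape "phylo" objects throughout, so Newick IO and tree manipulation use the
# standard toolset.

#' Pairwise p-distance matrix of a protein alignment
#'
#' Distance between two sequences is the fraction of mismatching columns
#' among columns where neither sequence has a gap. Pairs with no comparable
#' column get distance 1 with a warning.
#'
#' @param alignment named character vector of equal-length gapped protein
#'   strings (>= 3 sequences).
#' @return symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   names.
#' @export
p_distance_matrix <- function(alignment) {
  if (length(alignment) < 3L) stop_input("need >= 3 sequences for a distance matrix")
  if (length(unique(nchar(alignment))) != 1L) stop_input("ragged alignment")
  if (is.null(names(alignment))) names(alignment) <- paste0("seq", seq_along(alignment))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  gap <- mat == "-" | mat == "."
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        warning(sprintf("no comparable columns between %s and %s; distance set to 1",
                        names(alignment)[i], names(alignment)[j]), call. = FALSE)
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with Studier-Keppler distance
#' updates. At each step the pair minimizing the Q criterion is joined;
#' ties are broken by the lexicographically smallest (label_i, label_j)
#' pair, so the result is deterministic. Negative branch length estimates
#' are clamped to zero with the deficit moved to the sister branch (total
#' path length preserved).
#'
#' @param d symmetric distance matrix with labeled rows/columns (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop_input("distance matrix is not symmetric")
  n <- nrow(d)
  if (n < 3L) stop_input("need >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node bookkeeping: tips 1..n, internals n+1 .. 2n-2 (ape convention)
  active <- seq_len(n)            # current cluster -> node id
  node_next <- n + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  dm <- d
  cl_label <- labels              # label for deterministic tie-breaks
  while (length(active) > 3L) {
    m <- length(active)
    rs <- rowSums(dm)
    q <- (m - 2) * dm - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- paste(pmin(cl_label[cand[, 1]], cl_label[cand[, 2]]),
                  pmax(cl_label[cand[, 1]], cl_label[cand[, 2]]), sep = "\r")
    pick <- cand[order(keys)[1], ]
    i <- min(pick); j <- max(pick)
    dij <- dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- node_next; node_next <- node_next + 1L
    edges <- rbind(edges, c(new_node, active[i]), c(new_node, active[j]))
    lens <- c(lens, li, lj)
    # Studier-Keppler update
    dk <- (dm[i, ] + dm[j, ] - dij) / 2
    dk <- dk[-c(i, j)]
    dm <- dm[-c(i, j), -c(i, j), drop = FALSE]
    dm <- rbind(cbind(dm, dk), c(dk, 0))
    active <- c(active[-c(i, j)], new_node)
    cl_label <- c(cl_label[-c(i, j)], min(cl_label[c(i, j)]))
  }
  # final three clusters join at one internal node
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  for (v in c("la", "lb", "lc")) if (get(v) < 0) assign(v, 0)
  new_node <- node_next
  edges <- rbind(edges, c(new_node, active[1]), c(new_node, active[2]), c(new_node, active[3]))
  lens <- c(lens, la, lb, lc)
  # renumber internal nodes to ape convention: tips 1..n, root-ish node n+1
  internal <- sort(unique(edges[edges > n]))
  remap <- setNames(seq_along(internal) + n, internal)
  # ape expects the node introduced last (joining node) to be the lowest
  # internal number; reverse order of creation
  remap <- setNames(n + rev(seq_along(internal)), internal)
  e2 <- edges
  e2[e2 > n] <- remap[as.character(e2[e2 > n])]
  tree <- list(edge = e2[order(e2[, 1], e2[, 2]), , drop = FALSE],
               edge.length = unname(lens[order(e2[, 1], e2[, 2])]),
               tip.label = labels, Nnode = length(internal))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Summarize subfamily clades on a tree
#'
#' For each subfamily, finds the smallest clade (most recent common
#' ancestor) containing all its leaves and reports the monophyly fraction:
#' number of subfamily members in that clade divided by the clade size.
#' Leaves without a label are treated as `"species-specific"`.
#'
#' @param tree an `ape::phylo` tree.
#' @param subfamily named character vector: subfamily label per leaf label.
#' @return data.frame: `subfamily`, `n_members`, `clade_size`,
#'   `monophyly_fraction`.
#' @export
annotate_clades <- function(tree, subfamily) {
  stopifnot(inherits(tree, "phylo"))
  labs <- subfamily[tree$tip.label]
  labs[is.na(labs)] <- "species-specific"
  names(labs) <- tree$tip.label
  # rooted view for MRCA computations
  rt <- if (ape::is.rooted(tree)) tree else ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  rows <- lapply(sort(unique(labs)), function(sf) {
    members <- names(labs)[labs == sf]
    if (length(members) == 1L) {
      return(data.frame(subfamily = sf, n_members = 1L, clade_size = 1L,
                        monophyly_fraction = 1, stringsAsFactors = FALSE))
    }
    mrca <- ape::getMRCA(rt, members)
    clade_tips <- ape::extract.clade(rt, mrca)$tip.label
    data.frame(subfamily = sf, n_members = length(members),
               clade_size = length(clade_tips),
               monophyly_fraction = length(members) / length(clade_tips),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
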