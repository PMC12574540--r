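# Expression-profile transformation, Spearman-distance complete-linkage
# clustering, tissue specificity and gene-dosage summaries.

#' Construct an expression matrix with sample metadata
#'
#' @param values non-negative numeric matrix, genes x samples (FPKM).
#' @param meta data.frame with one row per sample: `sample_id`, `tissue`,
#'   `stage`, `replicate`.
#' @return object of class `expression_matrix`: list(values, meta).
#' @export
expression_matrix <- function(values, meta) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression values need gene rownames and sample colnames")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_input("negative expression value at gene %s, sample %s",
               rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]])
  }
  need <- c("sample_id", "tissue", "stage", "replicate")
  missing_col <- setdiff(need, names(meta))
  if (length(missing_col) > 0L) stop_input("sample metadata lacks column %s", missing_col[1])
  if (!setequal(meta$sample_id, colnames(values))) {
    stop_input("sample metadata does not cover the value columns")
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d tissues, %d stages)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$meta$tissue)), length(unique(x$meta$stage))))
  invisible(x)
}

#' log2(1 + x) transform of an expression matrix
#'
#' @param m an [expression_matrix()] (or bare numeric matrix).
#' @return the same container with values replaced by `log2(1 + x)`.
#' @export
log_transform <- function(m) {
  v <- if (inherits(m, "expression_matrix")) m$values else m
  neg <- which(v < 0, arr.ind = TRUE)
  if (length(neg) > 0) {
    stop_input("negative expression value at row %d, column %d", neg[1, 1], neg[1, 2])
  }
  v <- log2(1 + v)
  if (inherits(m, "expression_matrix")) { m$values <- v; m } else v
}

#' Average replicates per (tissue, stage) condition
#'
#' @param m an [expression_matrix()].
#' @return an [expression_matrix()] with one column per condition
#'   (`tissue.stage`), replicate column set to 1.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  cond <- paste(m$meta$tissue, m$meta$stage, sep = ".")
  groups <- split(seq_along(cond), cond)
  groups <- groups[unique(cond)]
  v <- vapply(groups, function(i) rowMeans(m$values[, i, drop = FALSE]),
              numeric(nrow(m$values)))
  v <- matrix(v, nrow = nrow(m$values),
              dimnames = list(rownames(m$values), names(groups)))
  first <- vapply(groups, `[[`, integer(1), 1L)
  meta <- data.frame(sample_id = names(groups),
                     tissue = m$meta$tissue[first],
                     stage = m$meta$stage[first],
                     replicate = 1L, stringsAsFactors = FALSE)
  expression_matrix(v, meta)
}

#' Cluster genes by Spearman distance with complete linkage
#'
#' Gene-gene distance is `1 - rho` (Spearman rank correlation, ties
#' mid-ranked), so identical rank profiles have distance 0 and perfectly
#' anti-ranked profiles distance 2. Constant gene vectors have undefined
#' correlation; their distances are set to 1 with a warning. Agglomeration
#' is complete linkage. Genes are sorted by id before clustering, so leaf
#' order is deterministic.
#'
#' @param m an [expression_matrix()] with >= 2 genes and >= 3 samples.
#' @param average_reps average replicates per condition first (default
#'   TRUE).
#' @param log use log2(1 + x) values (default TRUE; Spearman distances are
#'   invariant to this, it only affects the exported matrix).
#' @return list with `hclust` (stats::hclust object), `order` (gene ids in
#'   dendrogram order), `distance` (dist object), `values` (matrix used).
#' @export
cluster_genes <- function(m, average_reps = TRUE, log = TRUE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (nrow(m$values) < 2L) stop_input("need >= 2 genes to cluster")
  if (ncol(m$values) < 3L) stop_input("need >= 3 samples to cluster")
  if (average_reps) m <- average_replicates(m)
  if (log) m <- log_transform(m)
  v <- m$values[order(rownames(m$values)), , drop = FALSE]
  constant <- apply(v, 1, function(x) diff(range(x)) == 0)
  rho <- suppressWarnings(cor(t(v), method = "spearman"))
  if (any(constant)) {
    warning(sprintf("%d constant gene vector(s); their distances set to 1",
                    sum(constant)), call. = FALSE)
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "complete")
  list(hclust = hc, order = rownames(v)[hc$order], distance = d, values = v)
}

#' Tissue specificity (tau) per gene
#'
#' `tau = sum(1 - x_i / max(x)) / (n_tissues - 1)` over per-tissue mean
#' log-expression; 0 for uniform expression, 1 for strict single-tissue
#' expression. Genes with all-zero expression get `NA`.
#'
#' @param m an [expression_matrix()].
#' @param threshold tau at or above which a gene is called tissue-specific
#'   (default 0.85).
#' @return data.frame: `gene_id`, `tau`, `specific` (logical), `top_tissue`.
#' @export
tissue_tau <- function(m, threshold = 0.85) {
  stopifnot(inherits(m, "expression_matrix"))
  lt <- log_transform(m)
  tissues <- unique(lt$meta$tissue)
  per_tissue <- vapply(tissues, function(t) {
    rowMeans(lt$values[, lt$meta$tissue == t, drop = FALSE])
  }, numeric(nrow(lt$values)))
  per_tissue <- matrix(per_tissue, nrow = nrow(lt$values),
                       dimnames = list(rownames(lt$values), tissues))
  mx <- apply(per_tissue, 1, max)
  tau <- ifelse(mx > 0,
                rowSums(1 - per_tissue / ifelse(mx > 0, mx, 1)) / (length(tissues) - 1),
                NA_real_)
  data.frame(
    gene_id = rownames(per_tissue),
    tau = unname(tau),
    specific = !is.na(tau) & tau >= threshold,
    top_tissue = tissues[apply(per_tissue, 1, which.max)],
    stringsAsFactors = FALSE
  )
}

#' Gene-dosage expression summary for multi-copy gene sets
#'
#' For each copy set (e.g. the retained copies of one ancestral gene), the
#' per-tissue mean expression of every member and of the member sum, with
#' the tissue of maximal summed expression flagged.
#'
#' @param m an [expression_matrix()].
#' @param copy_groups named list: copy-set id -> character vector of member
#'   gene ids.
#' @return list with `members` (data.frame: copy_set, gene_id, tissue,
#'   mean_expr) and `sets` (data.frame: copy_set, n_copies, top_tissue,
#'   top_sum).
#' @export
dosage_summary <- function(m, copy_groups) {
  stopifnot(inherits(m, "expression_matrix"))
  unknown <- setdiff(unlist(copy_groups), rownames(m$values))
  if (length(unknown) > 0L) stop_input("copy set references unknown gene: %s", unknown[1])
  tissues <- unique(m$meta$tissue)
  per_tissue <- vapply(tissues, function(t) {
    rowMeans(m$values[, m$meta$tissue == t, drop = FALSE])
  }, numeric(nrow(m$values)))
  per_tissue <- matrix(per_tissue, nrow = nrow(m$values),
                       dimnames = list(rownames(m$values), tissues))
  members <- do.call(rbind, lapply(names(copy_groups), function(cs) {
    g <- copy_groups[[cs]]
    data.frame(copy_set = cs,
               gene_id = rep(g, each = length(tissues)),
               tissue = rep(tissues, times = length(g)),
               mean_expr = as.vector(t(per_tissue[g, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  sets <- do.call(rbind, lapply(names(copy_groups), function(cs) {
    g <- copy_groups[[cs]]
    sums <- colSums(per_tissue[g, , drop = FALSE])
    data.frame(copy_set = cs, n_copies = length(g),
               top_tissue = tissues[which.max(sums)],
               top_sum = max(sums), stringsAsFactors = FALSE)
  }))
  rownames(members) <- rownames(sets) <- NULL
  list(members = members, sets = sets)
}
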