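mk_genes <- function(n, genome = "G01", chrom = "chr01", start0 = 1, len = 300) {
  data.frame(
    gene_id = sprintf("%s_%s_g%03d.1", genome, chrom, seq_len(n)),
    genome_id = genome, chrom = chrom,
    start = start0 + (seq_len(n) - 1) * 1000L,
    end = start0 + (seq_len(n) - 1) * 1000L + len - 1L,
    strand = "+",
    locus_id = sprintf("%s_%s_g%03d", genome, chrom, seq_len(n)),
    cds_len = len,
    stringsAsFactors = FALSE
  )
}

sim_edges <- function(pairs, evalue = 1e-40) {
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             bitscore = 300, evalue = evalue, stringsAsFactors = FALSE)
}

test_that("isoform filtering keeps the longest CDS per locus", {
  g <- mk_genes(3)
  iso <- g[1, ]
  iso$gene_id <- sub("\\.1$", ".2", iso$gene_id)
  iso$cds_len <- 600L
  g$cds_len <- c(900L, 500L, 500L)
  both <- rbind(g, iso)
  kept <- filter_isoforms(both)
  expect_equal(nrow(kept), 3)
  expect_true(g$gene_id[1] %in% kept$gene_id)       # 900 beats 600
  expect_false(iso$gene_id %in% kept$gene_id)
  # ties go to the smallest gene id
  tie <- both; tie$cds_len <- 500L
  kept_tie <- filter_isoforms(tie)
  expect_true(g$gene_id[1] %in% kept_tie$gene_id)
  # no isoforms: unchanged gene set, ranks recomputed 0..n-1
  only <- filter_isoforms(g)
  expect_setequal(only$gene_id, g$gene_id)
  expect_equal(sort(only$rank), 0:2)
  # missing locus_id warns and keeps the model
  na_loc <- g; na_loc$locus_id[2] <- NA
  expect_warning(kept_na <- filter_isoforms(na_loc), "locus_id")
  expect_equal(nrow(kept_na), 3)
})

test_that("tandem detection respects chromosome and rank-gap constraints", {
  g <- mk_genes(20)
  # three mutually similar genes at consecutive ranks -> one array of 3
  e <- sim_edges(rbind(c(g$gene_id[10], g$gene_id[11]),
                       c(g$gene_id[10], g$gene_id[12]),
                       c(g$gene_id[11], g$gene_id[12])))
  arr <- detect_tandem_arrays(g, e, max_rank_gap = 1)
  expect_equal(length(unique(arr$array_id)), 1)
  expect_equal(arr$gene_id, g$gene_id[10:12])        # ordered by rank
  # same pair on different chromosomes -> nothing
  g2 <- rbind(mk_genes(5, chrom = "chr01"), mk_genes(5, chrom = "chr02"))
  e2 <- sim_edges(cbind(g2$gene_id[1], g2$gene_id[6]))
  expect_equal(nrow(detect_tandem_arrays(g2, e2)), 0)
  # ranks 5 and 12: joined only when the cutoff reaches their distance
  g3 <- mk_genes(15)
  e3 <- sim_edges(cbind(g3$gene_id[6], g3$gene_id[13]))  # ranks 5 and 12
  expect_equal(nrow(detect_tandem_arrays(g3, e3, max_rank_gap = 5)), 0)
  expect_equal(nrow(detect_tandem_arrays(g3, e3, max_rank_gap = 7)), 2)
  # E-value above the cutoff never joins
  e4 <- sim_edges(cbind(g3$gene_id[6], g3$gene_id[7]), evalue = 1e-10)
  expect_equal(nrow(detect_tandem_arrays(g3, e4, evalue_cut = 1e-20)), 0)
  expect_error(detect_tandem_arrays(g3, e4, evalue_cut = 0), "evalue_cut")
})

test_that("tandem clustering equals single-linkage closure on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    g <- mk_genes(30)
    npair <- sample(5:12, 1)
    idx <- t(replicate(npair, sample(30, 2)))
    pairs <- cbind(g$gene_id[idx[, 1]], g$gene_id[idx[, 2]])
    cutoff <- sample(2:6, 1)
    arr <- detect_tandem_arrays(g, sim_edges(pairs), max_rank_gap = cutoff)
    dist <- abs(idx[, 1] - idx[, 2])
    keep <- dist <= cutoff
    comp <- oracle_single_linkage(unique(as.vector(pairs[keep, , drop = FALSE])),
                                  pairs[keep, , drop = FALSE], dist[keep], cutoff)
    comp <- Filter(function(x) length(x) >= 2, comp)
    got <- split(arr$gene_id, arr$array_id)
    expect_equal(sort(unname(vapply(got, function(m) paste(sort(m), collapse = ","), ""))),
                 sort(unname(vapply(comp, function(m) paste(sort(m), collapse = ","), ""))))
  }
})

test_that("arrays partition their members and match the implanted truth", {
  sim <- shared_sim()
  fam <- sim_family_genes(sim)
  arr <- detect_tandem_arrays(fam, sim$edges)
  expect_false(any(duplicated(arr$gene_id)))
  got <- split(arr$gene_id, arr$array_id)
  want <- split(sim$tandem_truth$gene_id, sim$tandem_truth$truth_array)
  expect_equal(sort(unname(vapply(got, function(m) paste(sort(m), collapse = ","), ""))),
               sort(unname(vapply(want, function(m) paste(sort(m), collapse = ","), ""))))
  # a cutoff below the widest implanted spacing splits that array, never merges
  spacings <- vapply(sim$config$tandem_arrays, `[`, integer(1), 2)
  if (any(spacings > 1)) {
    arr_tight <- detect_tandem_arrays(fam, sim$edges, max_rank_gap = 1)
    expect_lte(length(unique(arr_tight$array_id)), length(want))
  }
})

two_genome_anchors <- function(n, order_b = seq_len(n), chrom_b = "chr01") {
  ga <- mk_genes(n, genome = "GA")
  gb <- mk_genes(n, genome = "GB", chrom = chrom_b)
  anchors <- data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id[order_b],
                        bitscore = 400, evalue = 1e-60, stringsAsFactors = FALSE)
  list(ga = ga, gb = gb, anchors = anchors)
}

test_that("collinear chaining finds full same-order and inverted blocks", {
  x <- two_genome_anchors(10)
  b <- chain_collinear_blocks(x$anchors, x$ga, x$gb)
  expect_equal(length(unique(b$block_id)), 1)
  expect_equal(nrow(b), 10)
  expect_equal(unique(b$orientation), "same")
  expect_equal(unique(b$score), 10L)
  # reversed gene order in genome B -> one inverted block
  xr <- two_genome_anchors(10, order_b = 10:1)
  br <- chain_collinear_blocks(xr$anchors, xr$ga, xr$gb)
  expect_equal(length(unique(br$block_id)), 1)
  expect_equal(unique(br$orientation), "inverted")
  # 4 collinear anchors with s = 5 -> nothing
  x4 <- two_genome_anchors(4)
  expect_equal(nrow(chain_collinear_blocks(x4$anchors, x4$ga, x4$gb, s = 5)), 0)
  expect_error(chain_collinear_blocks(x4$anchors, x4$ga, x4$gb, u = -1), "u")
  expect_error(chain_collinear_blocks(x4$anchors, x4$ga, x4$gb, s = 1), "s")
})

test_that("the gap rule u bounds skipped anchors on both genomes", {
  # anchors collinear but every other anchor missing on genome B:
  # index gaps of 2 pass with u = 1, fail with u = 0
  ga <- mk_genes(12, genome = "GA")
  gb <- mk_genes(12, genome = "GB")
  keep <- seq(1, 12, by = 2)
  anchors <- data.frame(gene_a = ga$gene_id[keep], gene_b = gb$gene_id[keep],
                        bitscore = 400, evalue = 1e-60, stringsAsFactors = FALSE)
  b1 <- chain_collinear_blocks(anchors, ga, gb, u = 1, s = 5)
  expect_equal(nrow(b1), 6)
  # with u = 0 the index gap of 2 between consecutive anchors is too wide
  b0 <- chain_collinear_blocks(anchors, ga, gb, u = 0, s = 5)
  expect_equal(nrow(b0), 0)
  # a wider gap (1 -> 4) on genome B needs u = 2; u = 1 drops that anchor
  anchors2 <- anchors
  anchors2$gene_b <- gb$gene_id[c(1, 4, 6, 8, 10, 12)]
  b2 <- chain_collinear_blocks(anchors2, ga, gb, u = 1, s = 5)
  expect_equal(nrow(b2), 5)
  b3 <- chain_collinear_blocks(anchors2, ga, gb, u = 2, s = 5)
  expect_equal(nrow(b3), 6)
})

test_that("greedy chaining matches the exhaustive longest-chain oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(8:16, 1)
    ga <- mk_genes(n, genome = "GA")
    gb <- mk_genes(n, genome = "GB")
    anchors <- data.frame(gene_a = ga$gene_id[sample(n)],
                          gene_b = gb$gene_id[sample(n)],
                          bitscore = 400, evalue = 1e-60, stringsAsFactors = FALSE)
    u <- sample(0:2, 1)
    x <- match(anchors$gene_a, ga$gene_id)
    y <- match(anchors$gene_b, gb$gene_id)
    longest <- max(oracle_longest_chain(x, y, u, dir = 1),
                   oracle_longest_chain(x, y, u, dir = -1))
    b <- chain_collinear_blocks(anchors, ga, gb, u = u, s = 2)
    got <- if (nrow(b) == 0) 0 else max(b$score)
    expect_equal(got, if (longest >= 2) longest else 0)
  }
})

test_that("copy retention counts distinct block regions and caps at 3", {
  sim <- shared_sim()
  tg <- sim$genes[sim$genes$genome_id == "G01", ]
  blocks <- chain_collinear_blocks(sim$anchor_edges, tg, sim$outgroup_genes,
                                   u = 20, s = 5)
  ret <- classify_copy_retention(blocks, sim$outgroup_genes, tg)
  truth <- setNames(sim$retention_truth$copy_count, sim$retention_truth$gene_id)
  expect_equal(unname(ret[names(truth)]), unname(truth))
  # invariance to block reporting order
  shuf <- blocks[sample(nrow(blocks)), ]
  expect_equal(classify_copy_retention(shuf, sim$outgroup_genes, tg), ret)
  # genes with no anchors are class 0
  ghost <- sim$outgroup_genes[1, ]
  ghost$gene_id <- "OUT_ghost"
  ret2 <- classify_copy_retention(blocks, rbind(sim$outgroup_genes, ghost), tg)
  expect_equal(unname(ret2["OUT_ghost"]), 0L)
})

test_that("duplication origin labels combine tandem and collinearity evidence", {
  g <- mk_genes(6)
  arrays <- data.frame(array_id = "A1", genome_id = "G01", chrom = "chr01",
                       gene_id = g$gene_id[1:2], rank = 0:1,
                       stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = "BLK0001", genome_a = "G01", genome_b = "OUT",
                       chrom_a = "chr01", chrom_b = "chrV01",
                       gene_a = g$gene_id[c(2, 3)], gene_b = c("o1", "o2"),
                       orientation = "same", score = 5L, stringsAsFactors = FALSE)
  retention <- c(o1 = 3L, o2 = 1L)
  res <- attribute_duplication_origin(g, arrays, blocks, retention)
  expect_equal(unname(res$origin[g$gene_id[1]]), "TD")
  expect_equal(unname(res$origin[g$gene_id[2]]), "both")  # array + multi-copy anchor
  expect_equal(unname(res$origin[g$gene_id[3]]), "none")  # single-copy anchor
  expect_equal(unname(res$origin[g$gene_id[4]]), "none")
  expect_equal(sum(res$summary$n), 6)
  bad <- arrays; bad$gene_id[1] <- "missing"
  expect_error(attribute_duplication_origin(g, bad), "missing")
})
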