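mk_pav <- function(presence, groups) {
  structure(list(presence = presence,
                 groups = groups[order(groups$group_order, groups$genome_id), ],
                 gene_counts = presence),
            class = "pav_matrix")
}

panel_groups <- function(sizes = c(WDR = 13, SP = 11, SLC = 12, SLL = 25)) {
  data.frame(genome_id = sprintf("G%02d", seq_len(sum(sizes))),
             group = rep(names(sizes), sizes),
             group_order = rep(seq_along(sizes), sizes),
             stringsAsFactors = FALSE)
}

test_that("orthogroup clustering handles singletons, cliques and cutoffs", {
  genes <- paste0("g", 1:5)
  none <- cluster_orthogroups(data.frame(gene_a = character(), gene_b = character(),
                                         bitscore = numeric(), evalue = numeric()),
                              genes)
  expect_equal(length(unique(none$ogg_id)), 5)
  clique <- expand.grid(gene_a = paste0("h", 1:6), gene_b = paste0("h", 1:6),
                        stringsAsFactors = FALSE)
  clique <- clique[clique$gene_a < clique$gene_b, ]
  clique$bitscore <- 200; clique$evalue <- 1e-40
  one <- cluster_orthogroups(clique, paste0("h", 1:6))
  expect_equal(length(unique(one$ogg_id)), 1)
  expect_equal(unique(one$ogg_id), "OG0000000")
  # an edge above the E-value cutoff does not join components
  weak <- data.frame(gene_a = "g1", gene_b = "g2", bitscore = 400, evalue = 1e-5)
  split2 <- cluster_orthogroups(weak, c("g1", "g2"), evalue_cut = 1e-20)
  expect_equal(length(unique(split2$ogg_id)), 2)
  expect_error(cluster_orthogroups(weak, "g1"), "unknown gene")
})

test_that("OGG ids rank by member count with OrthoFinder-style labels", {
  edges <- data.frame(
    gene_a = c("a1", "a1", "b1"),
    gene_b = c("a2", "a3", "b2"),
    bitscore = 200, evalue = 1e-40, stringsAsFactors = FALSE
  )
  memb <- cluster_orthogroups(edges, c("a1", "a2", "a3", "b1", "b2", "c1"))
  by_ogg <- split(memb$gene_id, memb$ogg_id)
  expect_equal(names(by_ogg), c("OG0000000", "OG0000001", "OG0000002"))
  expect_setequal(by_ogg$OG0000000, c("a1", "a2", "a3"))
  expect_setequal(by_ogg$OG0000001, c("b1", "b2"))
  expect_equal(by_ogg$OG0000002, "c1")
})

test_that("presence thresholds reproduce the published category definitions", {
  groups <- panel_groups()          # 61 genomes
  n <- nrow(groups)
  presence <- rbind(
    all61 = rep(1L, n),
    in60 = c(rep(1L, 60), 0L),
    in35 = c(rep(1L, 35), rep(0L, n - 35)),
    in2 = c(1L, 1L, rep(0L, n - 2)),
    in1 = c(1L, rep(0L, n - 1))
  )
  colnames(presence) <- groups$genome_id
  cats <- classify_oggs(mk_pav(presence, groups))
  expect_equal(unname(cats), c("core", "softcore", "dispensable", "dispensable", "private"))
  # invariant to genome column order
  perm <- sample(ncol(presence))
  cats2 <- classify_oggs(mk_pav(presence[, perm], groups))
  expect_equal(cats2, cats)
  expect_error(classify_oggs(presence[, 1, drop = FALSE]), "fewer than 2")
})

test_that("categories partition the OGG set and gene counts sum to the total", {
  sim <- shared_sim()
  fam <- sim_family_genes(sim)
  memb <- cluster_orthogroups(sim$edges, fam$gene_id)
  pav <- build_pav(memb, setNames(fam$genome_id, fam$gene_id), sim$groups)
  cats <- classify_oggs(pav)
  expect_equal(length(cats), length(unique(memb$ogg_id)))
  summ <- summarize_categories(cats, memb)
  expect_equal(sum(summ$n_oggs), length(cats))
  expect_equal(sum(summ$n_genes), nrow(memb))
})

test_that("group frequencies round half-up to integer percent", {
  sizes <- c(WDR = 13, SP = 11, SLC = 12, SLL = 25)
  groups <- panel_groups(sizes)
  # numerators whose rounded trajectory is the classic rising profile
  pres <- integer(61)
  pres[c(1:8, 14:23, 25:35, 37:61)] <- 1L  # 8/13, 10/11, 11/12, 25/25
  presence <- matrix(pres, nrow = 1, dimnames = list("OGx", groups$genome_id))
  f <- group_frequencies(mk_pav(presence, groups))
  expect_equal(unname(f["OGx", ]), c(62, 91, 92, 100))
  # everywhere and nowhere-in-one-group
  all1 <- matrix(1L, 1, 61, dimnames = list("OGy", groups$genome_id))
  expect_true(all(group_frequencies(mk_pav(all1, groups)) == 100))
  none_wdr <- all1; none_wdr[1, 1:13] <- 0L
  expect_equal(unname(group_frequencies(mk_pav(none_wdr, groups))[1, "WDR"]), 0)
})

test_that("monotone trend calls match the published rising/falling profiles", {
  f <- rbind(rising = c(62, 91, 92, 100),
             falling = c(100, 91, 83, 68),
             flat = c(80, 80, 80, 80),
             bumpy = c(50, 90, 70, 100),
             small = c(80, 81, 82, 83))
  colnames(f) <- c("WDR", "SP", "SLC", "SLL")
  tr <- detect_monotone_trends(f, c("WDR", "SP", "SLC", "SLL"))
  expect_equal(tr$rising, "rising")
  expect_equal(tr$falling, "falling")
  tr2 <- detect_monotone_trends(f, min_delta = 3)
  expect_setequal(tr2$rising, c("rising", "small"))
  expect_error(detect_monotone_trends(f, c("WDR", "SP")), ">= 3")
  expect_error(detect_monotone_trends(f, c("WDR", "SP", "XX", "SLL")), "unknown group")
})

test_that("gene-share percentages reproduce printed two-decimal figures", {
  expect_equal(gene_share_percent(7811, 10769), 72.53)
  expect_equal(gene_share_percent(3522, 10769, digits = 1), 32.7)
  expect_equal(gene_share_percent(4949, 10769, digits = 0), 46)
  expect_equal(gene_share_percent(3010, 10769, digits = 0), 28)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(-0.5), -1)
})

test_that("orthogroups clustering recovers simulator truth exactly", {
  sim <- shared_sim()
  fam <- sim_family_genes(sim)
  memb <- cluster_orthogroups(sim$edges, fam$gene_id)
  got <- setNames(memb$ogg_id, memb$gene_id)
  want <- setNames(sim$membership_truth$truth_ogg, sim$membership_truth$gene_id)
  expect_true(partitions_equal(as.list(got), as.list(want)))
})

test_that("an OrthoFinder-style membership table reads into the same layout", {
  tmp <- tempfile()
  writeLines(c("Orthogroup\tG01\tG02",
               "OG0000000\ta1, a2\tb1",
               "OG0000001\t\tb2"), tmp)
  memb <- read_orthogroups(tmp)
  expect_equal(nrow(memb), 4)
  expect_setequal(memb$gene_id[memb$ogg_id == "OG0000000"], c("a1", "a2", "b1"))
  expect_equal(memb$gene_id[memb$ogg_id == "OG0000001"], "b2")
})
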