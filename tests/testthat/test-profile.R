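toy_profile <- function(seqs, ...) build_profile(seqs, ...)

test_that("profile column scores follow the smoothed log-odds formula", {
  # two identical ungapped sequences, uniform background 1/20:
  # consensus residue score = log2(((2 + pc/20) / (2 + pc)) * 20)
  p <- build_profile(c("MKV", "MKV"), pseudocount = 1)
  expect_equal(p$length, 3)
  expect_equal(unname(p$scores["M", 1]), log2(((2 + 1 / 20) / (2 + 1)) * 20))
  expect_equal(unname(p$scores["A", 1]), log2(((0 + 1 / 20) / (2 + 1)) * 20))
  # 4-sequence alignment, hand-enumerated counts per column
  aln <- c("MKVA", "MKLA", "MRVA", "MKVG")
  p4 <- build_profile(aln, pseudocount = 1)
  sc <- function(count) log2(((count + 1 / 20) / (4 + 1)) * 20)
  expect_equal(unname(p4$scores["K", 2]), sc(3))
  expect_equal(unname(p4$scores["R", 2]), sc(1))
  expect_equal(unname(p4$scores["V", 3]), sc(3))
  expect_equal(unname(p4$scores["A", 4]), sc(3))
})

test_that("columns with more than half gaps are trimmed", {
  aln <- c("MA-", "MA-", "MAV", "M--", "M-V")
  # col 1: 0% gaps; col 2: 40% (kept); col 3: 60% (dropped)
  expect_equal(build_profile(aln)$length, 2)
  aln2 <- c("M-A", "M-A", "M-A", "MVA", "MV-")  # col 2 has 60% gaps -> dropped
  p <- build_profile(aln2)
  expect_equal(p$length, 2)
  expect_equal(p$kept_columns, c(1L, 3L))
  expect_error(build_profile(c("M", "MK")), "ragged")
  expect_error(build_profile(c("--", "--")), "all-gap")
})

test_that("consensus sequence attains the sum of per-column maxima", {
  set.seed(1)
  aln <- c("MKVANDE", "MKVGNDE", "MRVANDE", "MKVANDQ")
  p <- build_profile(aln)
  cons <- profile_consensus(p)
  expect_equal(score_sequence(p, cons), sum(apply(p$scores, 2, max)))
})

test_that("window scoring equals exhaustive offset enumeration", {
  set.seed(5)
  aa <- rownames(build_profile(c("MK", "MK"))$scores)
  for (rep in 1:8) {
    aln <- vapply(1:4, function(i) paste(sample(aa, 12, TRUE), collapse = ""), "")
    p <- build_profile(aln)
    s <- paste(sample(aa, 40, TRUE), collapse = "")
    expect_equal(score_sequence(p, s), oracle_window_score(p, s))
  }
})

test_that("the reported score dominates every fixed window placement", {
  set.seed(6)
  aa <- rownames(build_profile(c("MK", "MK"))$scores)
  aln <- vapply(1:3, function(i) paste(sample(aa, 10, TRUE), collapse = ""), "")
  p <- build_profile(aln)
  s <- paste(sample(aa, 25, TRUE), collapse = "")
  best <- score_sequence(p, s)
  chars <- strsplit(s, "")[[1]]
  for (start in 1:(25 - p$length + 1)) {
    idx <- match(chars[start:(start + p$length - 1)], rownames(p$scores))
    w <- sum(p$scores[cbind(idx, 1:p$length)])
    expect_lte(w, best + 1e-12)
  }
})

test_that("non-standard residues score zero with a warning", {
  p <- build_profile(c("MKV", "MKV"))
  expect_warning(s1 <- score_sequence(p, "MXV"), "non-standard")
  expect_equal(s1, unname(p$scores["M", 1] + p$scores["V", 3]))
})

test_that("a single-round scan reduces to a plain threshold sweep", {
  sim <- shared_sim()
  prof <- build_profile(unname(sim$seed_alignment))
  fam <- sim_family_genes(sim)
  g1 <- fam[fam$genome_id == "G01", ]
  proteome <- setNames(g1$protein[1:10], g1$gene_id[1:10])
  one <- iterative_scan(prof, proteome, rounds = 1, inclusion_threshold = 15)
  sweep <- vapply(proteome, function(s) score_sequence(prof, s), 0)
  expect_equal(setNames(one$hits$score, one$hits$id),
               sweep[sort(names(sweep))][sweep[sort(names(sweep))] >= 15])
})

test_that("iterative scan recovers the full family with perfect precision", {
  sim <- shared_sim()
  g1 <- filter_isoforms(sim$genes[sim$genes$genome_id == "G01", ])
  proteome <- setNames(g1$protein, g1$gene_id)
  prof <- build_profile(unname(sim$seed_alignment))
  res <- iterative_scan(prof, proteome)
  truth <- g1$gene_id[g1$is_family]
  expect_setequal(res$hits$id, truth)
  # seed sequences themselves are a fixed point
  seeds <- setNames(sim$seed_alignment, paste0("seed", seq_along(sim$seed_alignment)))
  fixed <- iterative_scan(prof, seeds, rounds = 3)
  expect_setequal(fixed$hits$id, names(seeds))
})

test_that("membership is monotone non-increasing in the inclusion threshold", {
  sim <- shared_sim()
  g1 <- filter_isoforms(sim$genes[sim$genes$genome_id == "G02", ])
  proteome <- setNames(g1$protein, g1$gene_id)[1:60]
  prof <- build_profile(unname(sim$seed_alignment))
  prev <- NULL
  for (thr in c(5, 15, 40, 120)) {
    hits <- iterative_scan(prof, proteome, rounds = 1,
                           inclusion_threshold = thr,
                           confident_threshold = max(thr, 25))$hits$id
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
  }
})

test_that("scan with no confident hits warns and reports nothing above inclusion", {
  p <- build_profile(c("WWWWWW", "WWWWWW"))
  expect_warning(res <- iterative_scan(p, c(a = "MKVMKV", b = "GGGGGG"),
                                       rounds = 2, inclusion_threshold = 15,
                                       confident_threshold = 25),
                 "no confident hits")
  expect_equal(nrow(res$hits), 0)
})

test_that("subfamily assignment picks the nearest reference or species-specific", {
  refs <- c(UGT73 = "MKVANDEQRSTLIVMKVANDEQRSTLIV",
            UGT85 = "WWFFYYHHPPGGCCWWFFYYHHPPGGCC")
  expect_equal(assign_subfamily(refs[["UGT73"]], refs), "UGT73")
  expect_equal(assign_subfamily("NNNNNNNNNNNNNNNNNNNNNNNNNNNN", refs, min_identity = 0.9),
               "species-specific")
  expect_error(assign_subfamily("", refs), "empty")
  # queries mutated from labeled references recover their source label
  sim <- shared_sim()
  set.seed(3)
  for (lab in names(sim$references)[1:6]) {
    cds_lab <- sim$references[[lab]]
    # mutate ~15% of residues
    v <- strsplit(cds_lab, "")[[1]]
    idx <- sample(length(v), round(0.15 * length(v)))
    v[idx] <- sample(c("A", "G", "S", "T", "L"), length(idx), TRUE)
    expect_equal(assign_subfamily(paste(v, collapse = ""), sim$references,
                                  min_identity = 0.4), lab)
  }
})

test_that("assignment does not depend on query order", {
  sim <- shared_sim()
  fam <- sim_family_genes(sim)
  queries <- fam$protein[1:5]
  fwd <- vapply(queries, assign_subfamily, "", references = sim$references)
  rev_ <- rev(vapply(rev(queries), assign_subfamily, "", references = sim$references))
  expect_equal(unname(fwd), unname(rev_))
})

test_that("domtblout adapter keeps the best score per target", {
  tmp <- tempfile()
  writeLines(c(
    "# comment line",
    paste("geneA", "-", "100", "PF00201", "-", "60", "1e-30", "95.2", "1", "1",
          "0.5", "1e-29", "1e-28", "94.0", "1", "60", "5", "64", "3", "66", "0.9"),
    paste("geneA", "-", "100", "PF00201", "-", "60", "1e-10", "41.0", "1", "1",
          "0.5", "1e-9", "1e-8", "40.0", "1", "60", "5", "64", "3", "66", "0.9"),
    paste("geneB", "-", "80", "PF00201", "-", "60", "1e-5", "20.5", "1", "1",
          "0.5", "1e-4", "1e-3", "19.0", "1", "60", "5", "64", "3", "66", "0.9")
  ), tmp)
  tab <- read_domtblout(tmp)
  expect_equal(tab$id, c("geneA", "geneB"))
  expect_equal(tab$score, c(95.2, 20.5))
})
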