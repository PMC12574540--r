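# Independent oracles, written as plain brute-force enumerations so they
# share no code path with the implementation they check.

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})
.oracle_stops <- names(.oracle_code)[.oracle_code == "*"]

# per-codon synonymous site count by direct enumeration of the 9 possible
# single-nucleotide changes, skipping changes into stop codons
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    ch <- strsplit(codon, "")[[1]]
    alts <- setdiff(c("A", "C", "G", "T"), ch[pos])
    variants <- vapply(alts, function(b) {
      v <- ch; v[pos] <- b; paste(v, collapse = "")
    }, character(1))
    variants <- variants[!(variants %in% .oracle_stops)]
    if (length(variants) == 0) next
    syn <- sum(.oracle_code[variants] == .oracle_code[[codon]])
    total <- total + syn / length(variants)
  }
  total
}

# all orderings of substitutions between two codons, as explicit paths;
# returns average (sd, nd) over stop-free paths
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(0, 0))
  orders <- if (length(pos) == 1) list(pos) else {
    perms <- as.matrix(expand.grid(rep(list(pos), length(pos))))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == length(pos)), , drop = FALSE]
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  }
  tallies <- list()
  for (ord in orders) {
    cur <- a; sd <- 0; nd <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% .oracle_stops) { hit_stop <- TRUE; break }
      if (.oracle_code[[from]] == .oracle_code[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!hit_stop) tallies[[length(tallies) + 1]] <- c(sd, nd)
  }
  if (length(tallies) == 0) return(NULL)  # caller decides on the degenerate case
  colMeans(do.call(rbind, tallies))
}

# full NG86 on a gap-free codon pair, assembled only from the two oracle
# primitives above
oracle_ng86 <- function(s1, s2) {
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- (sum(vapply(c1, oracle_syn_sites, 0)) + sum(vapply(c2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- oracle_pair_diffs(c1[i], c2[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  list(S = S, N = N, Sd = sd, Nd = nd, pS = sd / S, pN = nd / N)
}

# best gapless window score by explicit double loop over every offset
oracle_window_score <- function(profile, protein) {
  chars <- strsplit(protein, "")[[1]]
  L <- profile$length
  M <- length(chars)
  best <- -Inf
  for (off in (1 - L):(M - 1)) {
    s <- 0
    for (j in 1:L) {
      i <- off + j
      if (i >= 1 && i <= M && chars[i] %in% rownames(profile$scores)) {
        s <- s + profile$scores[chars[i], j]
      }
    }
    best <- max(best, s)
  }
  best
}

# exhaustive longest collinear chain by depth-first enumeration
oracle_longest_chain <- function(x, y, u, dir = 1) {
  n <- length(x)
  best <- 0
  extend <- function(last, len) {
    best <<- max(best, len)
    for (k in seq_len(n)) {
      dx <- x[k] - x[last]
      dy <- dir * (y[k] - y[last])
      if (dx >= 1 && dx <= u + 1 && dy >= 1 && dy <= u + 1) extend(k, len + 1)
    }
  }
  for (k in seq_len(n)) extend(k, 1)
  best
}

# transitive closure of "similar and within cutoff" pairs (single linkage
# with a hard cut), by repeated sweeps
oracle_single_linkage <- function(ids, pairs, dist, cutoff) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(pairs))) {
      if (dist[k] <= cutoff) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        if (comp[a] != comp[b]) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# exhaustive complete-linkage agglomeration: at each step merge the two
# clusters whose maximum inter-point distance is smallest
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random sense-codon CDS and a mutated partner with k random substitutions
# that never create stops (used to feed the NG86 oracle)
random_codon_pair <- function(n_codons, k) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  s1 <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  v <- strsplit(s1, "")[[1]]
  tries <- 0
  while (k > 0 && tries < 1000) {
    tries <- tries + 1
    i <- sample(length(v), 1)
    b <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    w <- v; w[i] <- b
    cods <- substring(paste(w, collapse = ""), seq(1, length(v), 3), seq(3, length(v), 3))
    if (!any(cods %in% .oracle_stops)) { v <- w; k <- k - 1 }
  }
  c(s1, paste(v, collapse = ""))
}

# shared small simulated pangenome, built once per test run
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- sim_config(n_genomes = 10, group_sizes = c(WDR = 3, SP = 3, SLC = 2, SLL = 2),
                      n_oggs = 50, n_outgroup_genes = 60, seed = 7)
    .shared$sim <- simulate_pangenome(cfg)
  }
  .shared$sim
}

sim_family_genes <- function(sim) {
  sim$genes[sim$genes$is_family & endsWith(sim$genes$gene_id, ".1"), , drop = FALSE]
}

# compare two partitions given as id -> cluster maps
partitions_equal <- function(a, b) {
  ids <- names(a)
  if (!setequal(ids, names(b))) return(FALSE)
  tab <- table(unlist(a[ids]), unlist(b[ids]))
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
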