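# Nei-Gojobori (1986) Ka/Ks on pairwise codon alignments.
#
# Site counting excludes single-nucleotide changes that would create a stop
# codon (they are removed from both numerator and denominator of the
# per-position synonymous fraction), and substitution pathways between
# diverged codons are averaged over all orderings that avoid stop codons.
# Proportions are Jukes-Cantor corrected: K = -(3/4) ln(1 - (4/3) p).

GENETIC_CODE_DNA <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

STOP_CODONS <- names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_DNA), STOP_CODONS)

translate_codon <- function(codon) unname(GENETIC_CODE_DNA[codon])

# Per-codon synonymous site count: for each of the 3 positions, the fraction
# of non-stop single-nucleotide changes that are synonymous; positions whose
# every non-stop change is nonsynonymous contribute 0. S + N = 3 always.
codon_syn_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; tot <- 0L
    for (b in setdiff(nt, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      if (alt_codon %in% STOP_CODONS) next
      tot <- tot + 1L
      if (GENETIC_CODE_DNA[[alt_codon]] == GENETIC_CODE_DNA[[codon]]) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  s
}

.syn_sites_table <- vapply(SENSE_CODONS, codon_syn_sites, numeric(1))

# single-nucleotide neighbor sets (stop codons excluded), split into
# synonymous and nonsynonymous, for every sense codon
.codon_neighbors <- local({
  nt <- c("A", "C", "G", "T")
  out <- lapply(SENSE_CODONS, function(codon) {
    chars <- strsplit(codon, "")[[1]]
    syn <- character(0); non <- character(0)
    for (pos in 1:3) {
      for (b in setdiff(nt, chars[pos])) {
        alt <- chars; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (alt %in% STOP_CODONS) next
        if (GENETIC_CODE_DNA[[alt]] == GENETIC_CODE_DNA[[codon]]) {
          syn <- c(syn, alt)
        } else non <- c(non, alt)
      }
    }
    list(syn = syn, non = non)
  })
  names(out) <- SENSE_CODONS
  out
})

# Average synonymous/nonsynonymous differences between two codons over all
# minimal substitution pathways that avoid stop codons. Returns c(sd, nd)
# with sd + nd = number of differing positions.
codon_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else {
    idx <- permutations_of(d)
    lapply(idx, function(i) pos[i])
  }
  tally <- function(order, skip_stops) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (to %in% STOP_CODONS) {
        if (skip_stops) { ok <- FALSE; break }
        # degenerate fallback: step through the stop without classifying it
        cur <- nxt
        next
      }
      if (from %in% STOP_CODONS) { cur <- nxt; next }
      if (GENETIC_CODE_DNA[[from]] == GENETIC_CODE_DNA[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) c(sd, nd) else NULL
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, skip_stops = TRUE))
  if (length(res) == 0L) {
    # every ordering passes through a stop codon: weight only the non-stop
    # steps of each pathway and rescale so counted differences sum to d
    res <- lapply(perms, tally, skip_stops = FALSE)
    m <- colMeans(do.call(rbind, res))
    tot <- sum(m)
    if (tot > 0) m <- m * d / tot
    warning(sprintf(
      "all substitution pathways between %s and %s pass through a stop codon; non-stop steps reweighted",
      c1, c2), call. = FALSE)
    return(c(sd = m[1], nd = m[2]))
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[1], nd = m[2])
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop_input("sequence length %d is not a multiple of 3", n)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Construct a pairwise codon alignment
#'
#' Both sequences must have equal length, a multiple of 3, with gaps (if any)
#' in whole-codon units (`---`). Terminal stop codons are trimmed from both
#' sequences; an internal stop in an ungapped column is an error.
#'
#' @param seq_a,seq_b aligned nucleotide strings.
#' @param id_a,id_b optional sequence identifiers.
#' @return object of class `codon_alignment`: list with per-codon character
#'   vectors `a`, `b` and ids.
#' @export
codon_alignment <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  a <- split_codons(seq_a)
  b <- split_codons(seq_b)
  if (length(a) != length(b)) {
    stop_input("aligned sequences differ in codon length (%d vs %d)", length(a), length(b))
  }
  # trim one terminal stop column if present in either row
  n <- length(a)
  if (n > 0 && (a[n] %in% STOP_CODONS || b[n] %in% STOP_CODONS)) {
    a <- a[-n]; b <- b[-n]
  }
  ungapped <- !grepl("-", a) & !grepl("-", b)
  internal_stop <- ungapped & (a %in% STOP_CODONS | b %in% STOP_CODONS)
  if (any(internal_stop)) {
    stop_input("internal stop codon at codon column %d", which(internal_stop)[1])
  }
  structure(list(a = a, b = b, id_a = id_a, id_b = id_b),
            class = "codon_alignment")
}

#' Nei-Gojobori Ka/Ks for one codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence with
#' stop-codon exclusion, averages the two sequences, counts synonymous (Sd)
#' and nonsynonymous (Nd) differences by averaging over all stop-avoiding
#' minimal substitution pathways, and applies the Jukes-Cantor correction to
#' the proportions pS = Sd/S and pN = Nd/N. Columns containing a gap in
#' either row, or an ambiguous nucleotide, are excluded from both sites and
#' differences.
#'
#' The ratio is `NA` (flagged `undefined`) when Ks = 0 or when a proportion
#' reaches the Jukes-Cantor divergence bound of 3/4.
#'
#' @param aln a [codon_alignment()].
#' @return a one-row data.frame of class `kaks_result` with columns
#'   `gene_a`, `gene_b`, `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `ratio`, `n_codons` (ungapped codon columns used).
#' @examples
#' ng86_pair(codon_alignment("TTTTTG", "TTCTTG"))  # one synonymous change
#' @export
ng86_pair <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  usable <- !grepl("-", aln$a) & !grepl("-", aln$b) &
    !grepl("[^ACGT]", aln$a) & !grepl("[^ACGT]", aln$b)
  a <- aln$a[usable]
  b <- aln$b[usable]
  if (length(a) == 0L) stop_input("no comparable (ungapped, unambiguous) codon columns")
  S_a <- sum(.syn_sites_table[a])
  S_b <- sum(.syn_sites_table[b])
  S <- (S_a + S_b) / 2
  N <- 3 * length(a) - S
  diff_cols <- which(a != b)
  sd <- 0; nd <- 0
  for (i in diff_cols) {
    d <- codon_pair_diffs(a[i], b[i])
    sd <- sd + d[[1]]
    nd <- nd + d[[2]]
  }
  # a stratum of zero sites can only carry zero differences
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
  Ks <- jc(pS)
  Ka <- jc(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  out <- data.frame(
    gene_a = aln$id_a, gene_b = aln$id_b,
    S_sites = S, N_sites = N, Sd = sd, Nd = nd,
    pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
    n_codons = length(a),
    stringsAsFactors = FALSE
  )
  class(out) <- c("kaks_result", "data.frame")
  out
}

#' Classify selection mode from a Ka/Ks ratio
#'
#' Ratios above 1 indicate positive selection, below 1 purifying selection
#' and near 1 neutral evolution. An undefined ratio (Ks = 0 or saturated
#' divergence) is reported as `"undefined"`, never forced to a class.
#'
#' @param result a `kaks_result` row (or any list with a `ratio` field).
#' @param tol half-width of the neutral band around 1 (default 1e-9, i.e.
#'   strict inequalities).
#' @return one of `"positive"`, `"purifying"`, `"neutral"`, `"undefined"`.
#' @export
classify_selection <- function(result, tol = 1e-9) {
  r <- result$ratio
  if (length(r) != 1L) stop_input("classify_selection() expects a single result")
  if (is.na(r)) return("undefined")
  if (r > 1 + tol) return("positive")
  if (r < 1 - tol) return("purifying")
  "neutral"
}

#' Back-translate a pairwise protein alignment to codons
#'
#' Each amino acid is replaced by its source codon and each protein gap by a
#' codon gap (`---`). Terminal stop codons are trimmed from the CDS before
#' validation. The translation of the output equals the input protein
#' alignment; any codon/amino-acid disagreement is an error naming the gene
#' and position.
#'
#' @param prot_a,prot_b aligned (gapped) protein strings of equal length.
#' @param cds_a,cds_b ungapped coding sequences of the two genes.
#' @param id_a,id_b gene identifiers used in messages and output.
#' @return a [codon_alignment()].
#' @export
back_translate <- function(prot_a, prot_b, cds_a, cds_b,
                           id_a = "seq_a", id_b = "seq_b") {
  if (nchar(prot_a) != nchar(prot_b)) {
    stop_input("protein alignment rows differ in length (%d vs %d)",
               nchar(prot_a), nchar(prot_b))
  }
  thread <- function(prot, cds, id) {
    codons <- split_codons(cds)
    n <- length(codons)
    if (n > 0 && codons[n] %in% STOP_CODONS) codons <- codons[-n]
    aa <- strsplit(toupper(prot), "")[[1]]
    if (sum(aa != "-") != length(codons)) {
      stop_input("gene %s: CDS has %d codons but protein alignment has %d residues",
                 id, length(codons), sum(aa != "-"))
    }
    out <- character(length(aa))
    j <- 0L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") {
        out[i] <- "---"
      } else {
        j <- j + 1L
        codon <- codons[j]
        tr <- if (grepl("[^ACGT]", codon)) "X" else translate_codon(codon)
        if (tr != "X" && tr != aa[i]) {
          stop_input("gene %s: codon %s at position %d translates to %s, expected %s",
                     id, codon, j, tr, aa[i])
        }
        out[i] <- codon
      }
    }
    paste(out, collapse = "")
  }
  codon_alignment(thread(prot_a, cds_a, id_a), thread(prot_b, cds_b, id_b),
                  id_a = id_a, id_b = id_b)
}

#' Stratified Ka/Ks summaries
#'
#' Means, medians and pair counts of Ka/Ks per (population group x
#' copy-retention class) cell, excluding pairs with undefined ratios (their
#' count is reported separately). Cells with no defined pair are emitted
#' with `n = 0` and `NA` mean.
#'
#' @param results data.frame of `kaks_result` rows (stacked).
#' @param retention named integer vector: copy count per outgroup gene
#'   (matched against `results$gene_a`).
#' @param groups named character vector: population group per genome; the
#'   genome of a pair is taken from `results$genome` if present, otherwise
#'   all pairs fall in group `"all"`.
#' @return data.frame with columns `group`, `copy_class`, `n`, `mean_ratio`,
#'   `median_ratio`, `n_undefined`.
#' @export
summarize_strata <- function(results, retention, groups = NULL) {
  stopifnot(is.data.frame(results))
  copy_class <- retention[results$gene_a]
  if (anyNA(copy_class)) {
    copy_class[is.na(copy_class)] <- 0L
  }
  copy_class <- ifelse(copy_class >= 3, "3", as.character(copy_class))
  group <- if (!is.null(results$genome) && !is.null(groups)) {
    unname(groups[results$genome])
  } else rep("all", nrow(results))
  cells <- expand.grid(group = unique(group), copy_class = sort(unique(copy_class)),
                       stringsAsFactors = FALSE)
  summ <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- group == cells$group[i] & copy_class == cells$copy_class[i]
    r <- results$ratio[sel]
    ok <- !is.na(r)
    data.frame(
      group = cells$group[i], copy_class = cells$copy_class[i],
      n = sum(ok),
      mean_ratio = if (any(ok)) mean(r[ok]) else NA_real_,
      median_ratio = if (any(ok)) median(r[ok]) else NA_real_,
      n_undefined = sum(sel) - sum(ok),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, summ)
}
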