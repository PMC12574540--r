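# Position-specific scoring profile for gene-family identification.
#
# A lightweight, fully self-contained analog of a profile-HMM domain search:
# a profile is a matrix of per-column log-odds scores over the 20 amino
# acids; a sequence is scored by the best gapless placement of the profile
# along it. Species-specific refinement re-estimates the profile from
# confident hits, mirroring the iterative build-and-rescan procedure used
# with hmmbuild/hmmsearch, without HMMER's insert/delete states or E-value
# calibration. Externally computed HMMER domtblout tables can be ingested
# instead via read_domtblout().

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a log-odds scoring profile from a protein alignment
#'
#' Columns with more than 50% gaps are dropped (trimming of poorly covered
#' columns, analogous to gap-based alignment trimming). Each retained column
#' scores residue `a` as
#' `log2( ((count_a + pseudocount * bg_a) / (n_resid + pseudocount)) / bg_a )`
#' where `n_resid` is the number of non-gap residues in the column and `bg`
#' is the background amino-acid frequency.
#'
#' @param alignment character vector of equal-length gapped protein strings
#'   (>= 2 sequences).
#' @param pseudocount smoothing weight (> 0, default 1).
#' @param background named numeric vector of background frequencies over the
#'   20 amino acids, summing to 1 (default uniform 1/20).
#' @param max_gap_frac columns with a gap fraction strictly above this are
#'   dropped (default 0.5).
#' @return object of class `profile_model`: list with `scores` (20 x L
#'   matrix), `background`, `length`, `kept_columns`.
#' @export
build_profile <- function(alignment, pseudocount = 1,
                          background = NULL, max_gap_frac = 0.5) {
  if (length(alignment) < 2L) stop_input("need >= 2 aligned sequences")
  if (pseudocount <= 0) stop_config("pseudocount", "must be > 0")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop_input("ragged alignment: sequence lengths %s", paste(unique(lens), collapse = ", "))
  }
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  if (abs(sum(background) - 1) > 1e-9) stop_config("background", "must sum to 1")
  background <- background[AA20]
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0L) stop_input("alignment has no column with <= 50%% gaps (all-gap profile)")
  scores <- vapply(keep, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    n <- length(col)
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount * background) / (n + pseudocount)
    log2(freq / background)
  }, numeric(20))
  rownames(scores) <- AA20
  structure(
    list(scores = scores, background = background,
         length = length(keep), kept_columns = keep),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d columns (consensus %s...)\n", x$length,
              substr(profile_consensus(x), 1, min(30, x$length))))
  invisible(x)
}

#' Consensus sequence of a profile (highest-scoring residue per column)
#' @param profile a [build_profile()] result.
#' @return character string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  paste(AA20[apply(profile$scores, 2, which.max)], collapse = "")
}

#' Best gapless-window profile score of a sequence
#'
#' Slides the profile along the sequence over every offset, including
#' partial overlaps at the sequence ends where unmatched profile columns
#' score 0, and returns the maximum summed log-odds (bits). Characters
#' outside the 20 standard amino acids score 0 (background odds) with a
#' warning.
#'
#' @param profile a `profile_model`.
#' @param protein protein string (length >= 1).
#' @param details if `TRUE`, also return the best offset and the residues
#'   aligned to each profile column (gap-padded at overhangs).
#' @return numeric score in bits, or a list if `details = TRUE`.
#' @export
score_sequence <- function(profile, protein, details = FALSE) {
  stopifnot(inherits(profile, "profile_model"))
  if (nchar(protein) < 1L) stop_input("empty protein sequence")
  L <- profile$length
  if (L == 0L) return(if (details) list(score = 0, offset = 0L, window = "") else 0)
  chars <- strsplit(toupper(protein), "")[[1]]
  M <- length(chars)
  unknown <- !(chars %in% AA20)
  if (any(unknown)) {
    warning(sprintf("%d non-standard residue(s) scored at background odds", sum(unknown)),
            call. = FALSE)
  }
  # residue index per position (NA for unknown -> scores 0)
  ridx <- match(chars, AA20)
  best <- -Inf; best_off <- 0L
  for (off in (1L - L):(M - 1L)) {
    j <- max(1L, 1L - off):min(L, M - off)
    ri <- ridx[off + j]
    ok <- !is.na(ri)
    s <- sum(profile$scores[cbind(ri[ok], j[ok])])
    if (s > best) { best <- s; best_off <- off }
  }
  if (!details) return(best)
  window <- vapply(1:L, function(j) {
    i <- best_off + j
    if (i < 1L || i > M) "-" else chars[i]
  }, character(1))
  list(score = best, offset = best_off, window = paste(window, collapse = ""))
}

#' Iterative profile search of a proteome
#'
#' Round 1 scans every protein with the seed profile. Hits at or above
#' `confident_threshold` are anchored at their best-scoring window (gapless,
#' padded at overhangs) and rebuilt into a species-specific profile, which
#' drives the next round. The final round reports every sequence scoring at
#' or above `inclusion_threshold`.
#'
#' @param seed_profile a `profile_model` built from the family seed
#'   alignment.
#' @param proteome named character vector of protein sequences.
#' @param rounds number of scan rounds (>= 1; `rounds = 1` is a plain sweep
#'   with no rebuild).
#' @param inclusion_threshold bit score for final membership (default 15).
#' @param confident_threshold bit score for profile rebuilding (default 25;
#'   must be >= `inclusion_threshold`).
#' @param keep_list optional character vector of ids; when supplied, hits
#'   outside it are dropped after the final round (externally validated
#'   keep-list, e.g. from a domain-annotation service).
#' @return list with `hits` (data.frame id, score), `profile` (final
#'   `profile_model`).
#' @export
iterative_scan <- function(seed_profile, proteome, rounds = 2,
                           inclusion_threshold = 15, confident_threshold = 25,
                           keep_list = NULL) {
  if (!is_count(rounds, min = 1)) stop_config("rounds", "must be a count >= 1")
  if (confident_threshold < inclusion_threshold) {
    stop_config("confident_threshold", "must be >= inclusion_threshold")
  }
  if (is.null(names(proteome))) stop_input("proteome must be a named vector")
  profile <- seed_profile
  ids <- sort(names(proteome))
  scores <- NULL
  for (r in seq_len(rounds)) {
    det <- lapply(ids, function(id) score_sequence(profile, proteome[[id]], details = TRUE))
    scores <- vapply(det, `[[`, numeric(1), "score")
    if (r == rounds) break
    confident <- which(scores >= confident_threshold)
    if (length(confident) < 2L) {
      if (length(confident) == 0L && r == 1L) {
        warning("no confident hits in round 1; profile not rebuilt", call. = FALSE)
        if (!any(scores >= inclusion_threshold)) {
          return(list(hits = data.frame(id = character(), score = numeric(),
                                        stringsAsFactors = FALSE),
                      profile = profile))
        }
      } else {
        warning(sprintf("round %d: < 2 confident hits; keeping previous profile", r),
                call. = FALSE)
      }
      next
    }
    windows <- vapply(det[confident], `[[`, character(1), "window")
    profile <- build_profile(windows, background = profile$background)
  }
  sel <- scores >= inclusion_threshold
  hits <- data.frame(id = ids[sel], score = scores[sel], stringsAsFactors = FALSE)
  if (!is.null(keep_list)) hits <- hits[hits$id %in% keep_list, , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, profile = profile)
}

#' Assign a subfamily label by nearest reference sequence
#'
#' Global (Needleman-Wunsch) alignment identity against every reference;
#' the query takes the label of the best reference if identity reaches
#' `min_identity`, otherwise `"species-specific"`. Ties are broken by the
#' lexicographically first label.
#'
#' @param protein query protein string.
#' @param references named character vector: reference protein sequences,
#'   names are subfamily labels (possibly repeated across members).
#' @param min_identity minimum global identity fraction (default 0.4).
#' @return subfamily label (character scalar).
#' @export
assign_subfamily <- function(protein, references, min_identity = 0.4) {
  if (length(references) == 0L) stop_input("reference set is empty")
  if (nchar(protein) == 0L) stop_input("empty query protein")
  q <- Biostrings::AAString(protein)
  idents <- vapply(references, function(ref) {
    aln <- Biostrings::pairwiseAlignment(q, Biostrings::AAString(ref),
                                         type = "global",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(aln, type = "PID1") / 100
  }, numeric(1))
  best <- max(idents)
  if (best < min_identity) return("species-specific")
  labs <- names(references)[idents == best]
  sort(labs)[1]
}

#' Read a HMMER domtblout table (adapter)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout` and returns per-target best bit scores, so that
#' externally computed domain searches can replace [iterative_scan()]
#' scoring.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `score` (best full-sequence bit
#'   score per target).
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 14L)
  if (length(bad) > 0L) stop_input("malformed domtblout line %d", bad[1])
  df <- data.frame(
    id = vapply(fields, `[[`, character(1), 1L),
    score = as.numeric(vapply(fields, `[[`, character(1), 8L)),
    stringsAsFactors = FALSE
  )
  best <- aggregate(score ~ id, df, max)
  best[order(best$id), , drop = FALSE]
}
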