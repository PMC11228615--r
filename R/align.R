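# Anchored pairwise alignment onto the reference coordinate system.
#
# Queries are never re-aligned into a full multiple alignment; instead
# each query is globally aligned (affine gap penalties) against the
# best-scoring packaged reference row, which projects it into the shared
# 380-column space.  Motif extraction, logos and distance matrices all
# operate on that projection, so column semantics are stable across
# queries without an external aligner.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment of two amino-acid sequences.  A gap of
#' length L costs \code{gap_open + gap_extend * L}.  The optimum is found by
#' \code{Biostrings::pairwiseAlignment}; the returned alignment is
#' deterministic for identical inputs.
#'
#' @param query,reference Amino-acid strings (standard letters plus X).
#' @param substitution_table Name of the substitution matrix
#'   (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   defaults 11 and 1.
#' @return A \code{kr_alignment} list: \code{score}, gapped
#'   \code{query_aligned} and \code{reference_aligned} strings.
#' @examples
#' global_align("LDD", "LDD")$score
#' global_align("LD", "LDD")
#' @export
global_align <- function(query, reference, substitution_table = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(reference))
    stop("cannot align an empty sequence", call. = FALSE)
  .check_aa(query, "query"); .check_aa(reference, "reference")
  pa <- Biostrings::pairwiseAlignment(
    pattern = toupper(query), subject = toupper(reference),
    substitutionMatrix = substitution_table,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  structure(list(
    score = as.numeric(Biostrings::score(pa)),
    query_aligned = as.character(Biostrings::alignedPattern(pa)),
    reference_aligned = as.character(Biostrings::alignedSubject(pa))),
    class = "kr_alignment")
}

#' @export
print.kr_alignment <- function(x, ...) {
  cat(sprintf("global alignment, score %.1f\n", x$score))
  cat("  query: ", x$query_aligned, "\n  ref:   ", x$reference_aligned, "\n")
  invisible(x)
}

# score-only global alignment of many queries against every reference
# row (vectorized in C); returns a queries x references score matrix
.reference_scores <- function(seqs, profile,
                              substitution_table = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  qs <- Biostrings::AAStringSet(toupper(seqs))
  sc <- vapply(names(profile$sequences), function(rid)
    Biostrings::pairwiseAlignment(
      pattern = qs, subject = profile$sequences[[rid]],
      substitutionMatrix = substitution_table,
      gapOpening = gap_open, gapExtension = gap_extend,
      type = "global", scoreOnly = TRUE),
    numeric(length(seqs)))
  matrix(sc, nrow = length(seqs),
         dimnames = list(NULL, names(profile$sequences)))
}

# project a global alignment into reference-column space;
# returns per-reference-column query residue ("-" where deleted)
.alignment_column_map <- function(aln, ref_is_ungapped_row = TRUE) {
  q <- strsplit(aln$query_aligned, "")[[1]]
  r <- strsplit(aln$reference_aligned, "")[[1]]
  keep <- !.is_gap(r)
  q[keep]
}

#' Map a query KR sequence onto the reference columns
#'
#' Aligns the query against every reference row, keeps the best-scoring
#' one, and returns the query residue observed at each reference column
#' (gap where the query has a deletion).  A query covering less than
#' \code{min_coverage} of the reference columns is rejected as unalignable,
#' which usually signals a non-KR input.
#'
#' @param query A sequence string, or one row of a \code{\link{kr_dataset}}.
#' @param profile A \code{\link{kr_reference_profile}}.
#' @param min_coverage Minimum fraction of reference columns that must be
#'   occupied by query residues (default 0.5).
#' @param substitution_table,gap_open,gap_extend Passed to
#'   \code{\link{global_align}}.
#' @return A \code{kr_anchored} object: \code{id}, \code{map} (character
#'   vector, one residue or \code{"-"} per reference column),
#'   \code{score}, \code{coverage}, \code{best_reference}.
#' @export
anchor_map <- function(query, profile, min_coverage = 0.5,
                       substitution_table = "BLOSUM62",
                       gap_open = 11, gap_extend = 1,
                       reference_id = NULL) {
  id <- "query"
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    id <- query$id
    query <- query$sequence
  }
  if (is.null(reference_id)) {
    sc <- .reference_scores(query, profile, substitution_table,
                            gap_open, gap_extend)
    reference_id <- colnames(sc)[which.max(sc[1L, ])]
  }
  best_rid <- reference_id
  best <- global_align(query, profile$sequences[[best_rid]],
                       substitution_table, gap_open, gap_extend)
  map <- .alignment_column_map(best)
  stopifnot(length(map) == profile$ncol)
  coverage <- mean(!.is_gap(map))
  if (coverage < min_coverage)
    stop(sprintf(
      "unalignable query '%s': reference coverage %.2f below %.2f (probable non-KR input)",
      id, coverage, min_coverage), call. = FALSE)
  structure(list(id = id, map = map, score = best$score,
                 coverage = coverage, best_reference = best_rid,
                 alignment = best),
            class = "kr_anchored")
}

#' @export
print.kr_anchored <- function(x, ...) {
  cat(sprintf("anchored query '%s': best reference %s, score %.1f, coverage %.2f\n",
              x$id, x$best_reference, x$score, x$coverage))
  invisible(x)
}

#' Split a KR sequence into its structural and catalytic subdomains
#'
#' KR domains comprise a structural subdomain (KR_S) and a catalytic
#' subdomain (KR_C); in delta-modules an ER domain separates the two.  The
#' query is anchored to the reference columns and cut at the packaged
#' KR_S/KR_C boundary; query insertions are assigned to the subdomain of
#' the preceding reference column.  If more than 90\% of the KR_S columns
#' are gapped the input is assumed to be a KR_C-only sequence: an empty
#' KR_S is returned with a warning.
#'
#' @inheritParams anchor_map
#' @return A list with elements \code{KR_S} and \code{KR_C}; their
#'   concatenation restores the input sequence.
#' @export
split_subdomains <- function(query, profile, ...) {
  if (is.data.frame(query)) query <- query$sequence
  anc <- anchor_map(query, profile, ...)
  aln <- anc$alignment
  q <- strsplit(aln$query_aligned, "")[[1]]
  r <- strsplit(aln$reference_aligned, "")[[1]]
  refpos <- cumsum(!.is_gap(r))           # 0 before the first ref column
  in_krc <- refpos >= anc$krc_start %||% profile$krc_start
  take <- !.is_gap(q)
  kr_s <- paste(q[take & !in_krc], collapse = "")
  kr_c <- paste(q[take & in_krc], collapse = "")

  krs_cols <- anc$map[seq_len(profile$krc_start - 1L)]
  if (mean(.is_gap(krs_cols)) > 0.9) {
    warning("KR_S columns are >90% gapped; returning empty KR_S ",
            "(input looks like a KR_C-only sequence)", call. = FALSE)
    kr_c <- paste0(kr_s, kr_c)
    kr_s <- ""
  }
  list(KR_S = kr_s, KR_C = kr_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
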