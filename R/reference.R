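# Packaged reference coordinate system.
#
# All motif positions are addressed as columns of a fixed 380-column
# reference alignment: columns 1-150 hold the structural subdomain (KR_S,
# truncated Rossmann fold, no NADPH site), columns 151-380 the catalytic
# subdomain (KR_C, intact Rossmann fold with the catalytic Y/K pair and
# the glycine-rich NADPH-binding site).  The packaged seed set is a
# SYNTHETIC construction: eight ungapped rows sharing a common scaffold,
# one or two per stereotype (A1 primary, A1 variant, A2, B1, B1 variant,
# B2, C1, C2), whose anchor columns carry the literal fingerprint motifs
# (LDD in B rows, W in A rows, catalytic Y, K, GM, RLXR, G-rich NADPH
# site).  It stands in for a curated set of published KR sequences and is
# calibrated once against the literal motif strings; files are stored
# under inst/extdata with a "synthetic" label in their names.

.KR_REF_NCOL <- 380L
.KR_KRC_START <- 151L

# deterministic scaffold + reference rows (used once to write extdata,
# and by tests that need to rebuild the rows from first principles)
.kr_build_reference <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(4217L)

  anchors <- .kr_anchor_table()
  anchor_cols <- unlist(mapply(seq, anchors$start, anchors$end,
                               SIMPLIFY = FALSE))
  scaffold <- sample(AA20, .KR_REF_NCOL, replace = TRUE)

  set_anchors <- function(chars, stereotype) {
    pools <- .kr_type_anchor_pools(stereotype)
    for (a in names(pools)) {
      i <- match(a, anchors$anchor)
      cols <- seq(anchors$start[i], anchors$end[i])
      chars[cols] <- vapply(pools[[a]], function(p) p[[1L]], character(1))
    }
    chars
  }
  scaffold <- set_anchors(scaffold, "A1")

  rows <- list(REF_A1a = "A1", REF_A1b = "A1", REF_A2 = "A2",
               REF_B1a = "B1", REF_B1b = "B1", REF_B2 = "B2",
               REF_C1 = "C1",  REF_C2 = "C2")
  seqs <- vapply(names(rows), function(id) {
    chars <- scaffold
    if (id != "REF_A1a") {  # ~4% background divergence off the scaffold
      mut <- setdiff(which(stats::runif(.KR_REF_NCOL) < 0.04), anchor_cols)
      chars[mut] <- vapply(chars[mut], .mutate_residue, character(1))
    }
    paste(set_anchors(chars, rows[[id]]), collapse = "")
  }, character(1))

  list(sequences = seqs,
       types = unlist(rows),
       primary = "REF_A1a")
}

#' Load the packaged reference profile
#'
#' Reads the synthetic reference seed alignment and its anchor-coordinate
#' table, validates that the fingerprint anchors carry the literal motifs
#' they are named for (\code{LDD} at motif 2 in a B-type row, \code{W} at
#' motif 7 in an A-type row), and returns the profile used by
#' \code{\link{anchor_map}}, \code{\link{kr_predict_batch}} and the logo
#' and tree modes.
#'
#' @param fasta,anchors Optional paths to a replacement aligned FASTA
#'   (ungapped or gapped rows of equal width, headers carrying
#'   \code{type=} and optionally \code{primary=yes}) and anchor TSV
#'   (columns \code{anchor}, \code{motif}, \code{region},
#'   \code{start_col}, \code{end_col}; 1-based inclusive coordinates).
#'   Defaults to the packaged synthetic seed set.
#' @return A \code{kr_profile} object: reference sequences, per-row
#'   stereotype labels, the primary reference id, the KR_S/KR_C boundary
#'   column and the anchor table.
#' @examples
#' prof <- kr_reference_profile()
#' prof
#' @export
kr_reference_profile <- function(fasta = NULL, anchors = NULL) {
  if (is.null(fasta))
    fasta <- system.file("extdata", "kr_reference_synthetic.fasta",
                         package = "krstereo", mustWork = TRUE)
  if (is.null(anchors))
    anchors <- system.file("extdata", "kr_anchors.tsv",
                           package = "krstereo", mustWork = TRUE)

  aa <- Biostrings::readAAStringSet(fasta)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  get_field <- function(field) {
    m <- regmatches(headers, regexpr(paste0(field, "=\\S+"), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(field, "="), headers)
    out[hit] <- sub(paste0(field, "="), "", m)
    out
  }
  types <- get_field("type")
  primary <- ids[which(get_field("primary") == "yes")[1L]]
  if (is.na(primary)) primary <- ids[1L]
  seqs <- as.character(aa)
  names(seqs) <- ids
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("reference rows must share one alignment width", call. = FALSE)
  ncol <- unique(widths)

  at <- utils::read.delim(anchors, comment.char = "#",
                          stringsAsFactors = FALSE)
  bnd <- at$anchor == "subdomain_boundary"
  krc_start <- if (any(bnd)) at$start_col[bnd][1L] else .KR_KRC_START
  at <- at[!bnd, , drop = FALSE]
  anchor_tab <- data.frame(anchor = at$anchor, motif = at$motif,
                           region = at$region, start = at$start_col,
                           end = at$end_col, stringsAsFactors = FALSE)

  profile <- structure(list(sequences = seqs, types = types,
                            primary = primary, ncol = ncol,
                            krc_start = krc_start, anchors = anchor_tab),
                       class = "kr_profile")
  .validate_profile(profile)
  profile
}

.validate_profile <- function(profile) {
  at <- profile$anchors
  if (any(at$end > profile$ncol))
    stop("anchor columns exceed the alignment width", call. = FALSE)
  krc_anchors <- at$start[at$anchor != "motif1" | TRUE]
  if (profile$krc_start > min(at$start))
    stop("subdomain boundary must precede all KR_C fingerprint anchors",
         call. = FALSE)
  col_read <- function(seq, i) {
    cols <- seq(at$start[i], at$end[i])
    paste(strsplit(seq, "")[[1]][cols], collapse = "")
  }
  i2 <- match("motif2", at$anchor); i7 <- match("motif7", at$anchor)
  b_rows <- profile$sequences[grepl("^B", profile$types)]
  a_rows <- profile$sequences[grepl("^A", profile$types)]
  if (!any(vapply(b_rows, col_read, character(1), i = i2) == "LDD"))
    stop("no B-type reference row reads LDD at the motif-2 columns",
         call. = FALSE)
  if (!any(vapply(a_rows, col_read, character(1), i = i7) == "W"))
    stop("no A-type reference row reads W at the motif-7 column",
         call. = FALSE)
  if (!profile$primary %in% names(profile$sequences))
    stop("primary reference id not found among the rows", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.kr_profile <- function(x, ...) {
  cat(sprintf(
    "KR reference profile (synthetic seed set): %d rows x %d columns\n",
    length(x$sequences), x$ncol))
  cat(sprintf("  KR_S columns 1-%d, KR_C columns %d-%d\n",
              x$krc_start - 1L, x$krc_start, x$ncol))
  cat(sprintf("  primary reference: %s (%s-type)\n", x$primary,
              x$types[match(x$primary, names(x$sequences))]))
  cat(sprintf("  rows: %s\n",
              paste(sprintf("%s[%s]", names(x$sequences), x$types),
                    collapse = " ")))
  cat(sprintf("  anchors: %d (motifs 1-13 + NADPH site)\n",
              nrow(x$anchors)))
  invisible(x)
}

# residues of one reference row at one anchor
.profile_anchor_residues <- function(profile, row_id, anchor) {
  at <- profile$anchors
  i <- match(anchor, at$anchor)
  chars <- strsplit(profile$sequences[[row_id]], "")[[1]]
  paste(chars[seq(at$start[i], at$end[i])], collapse = "")
}
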