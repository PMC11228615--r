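# Sequence-logo statistics: per-column residue frequencies and
# information content, for motif re-derivation and verification.

#' Per-column information content in bits
#'
#' The standard logo measure \eqn{R = \log_2 20 - H - e_n} with
#' \eqn{H = -\sum_r f_r \log_2 f_r} and the optional small-sample
#' correction \eqn{e_n = 19 / (2 \ln 2 \cdot n)}; clamped at zero.
#'
#' @param freqs Frequency vector (sums to 1 over observed residues; an
#'   all-zero vector yields 0 bits).
#' @param n Number of residues the column was estimated from (used only
#'   by the correction).
#' @param small_sample_correction Apply \eqn{e_n}? Default \code{FALSE}.
#' @return Information content in bits, in [0, log2(20)].
#' @examples
#' information_content(c(1))            # log2(20) = 4.3219
#' information_content(rep(1/20, 20))   # 0
#' @export
information_content <- function(freqs, n = Inf,
                                small_sample_correction = FALSE) {
  f <- freqs[freqs > 0]
  if (length(f) == 0L) return(0)
  H <- -sum(f * log2(f))
  R <- log2(20) - H
  if (small_sample_correction && is.finite(n) && n > 0)
    R <- R - 19 / (2 * log(2) * n)
  max(R, 0)
}

#' Column frequencies and logo statistics for aligned rows
#'
#' Per column: residue frequencies normalized over non-gap letters, the
#' gap fraction, information content in bits, and per-residue stack
#' heights (frequency times information).  The column's width weight,
#' \code{1 - gap fraction}, mirrors the convention that a logo column's
#' width reflects how many sequences actually carry a residue there.
#'
#' @param rows Equal-length aligned sequences: character vector of
#'   strings, or a character matrix (rows = sequences).
#' @param small_sample_correction Passed to
#'   \code{\link{information_content}} (default \code{FALSE}).
#' @return A \code{kr_logo} object: \code{freq} (20 x L matrix),
#'   \code{gap_fraction}, \code{info} (bits), \code{heights}
#'   (20 x L), \code{width_weight}, \code{n}.
#' @export
kr_logo <- function(rows, small_sample_correction = FALSE) {
  if (is.character(rows) && !is.matrix(rows)) {
    if (length(rows) == 0L) stop("no rows", call. = FALSE)
    if (length(unique(nchar(rows))) != 1L)
      stop("rows must have equal length", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
  } else mat <- rows
  n <- nrow(mat); L <- ncol(mat)
  if (is.null(L) || L == 0L) {
    return(structure(list(freq = matrix(0, 20, 0, dimnames = list(AA20, NULL)),
                          gap_fraction = numeric(0), info = numeric(0),
                          heights = matrix(0, 20, 0,
                                           dimnames = list(AA20, NULL)),
                          width_weight = numeric(0), n = n),
                     class = "kr_logo"))
  }
  freq <- matrix(0, 20, L, dimnames = list(AA20, NULL))
  gapf <- numeric(L); info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gaps <- .is_gap(col) | col == "X"
    gapf[j] <- mean(.is_gap(col))
    obs <- col[!gaps & col %in% AA20]
    if (length(obs) > 0L) {
      tab <- table(factor(obs, levels = AA20))
      freq[, j] <- as.numeric(tab) / length(obs)
      info[j] <- information_content(freq[, j], n = length(obs),
                                     small_sample_correction)
    }
  }
  structure(list(freq = freq, gap_fraction = gapf, info = info,
                 heights = freq * rep(info, each = 20),
                 width_weight = 1 - gapf, n = n),
            class = "kr_logo")
}

#' @export
print.kr_logo <- function(x, ...) {
  L <- ncol(x$freq)
  cat(sprintf("sequence logo: %d columns from %d rows; mean info %.2f bits\n",
              L, x$n, if (L) mean(x$info) else NA_real_))
  invisible(x)
}

#' Tallest letter per logo column
#'
#' @param logo A \code{\link{kr_logo}}.
#' @param columns Column indices (default all).
#' @return Character vector of the most frequent residue per column
#'   (\code{NA} for all-gap columns).
#' @export
logo_consensus <- function(logo, columns = seq_len(ncol(logo$freq))) {
  vapply(columns, function(j) {
    f <- logo$freq[, j]
    if (all(f == 0)) NA_character_ else AA20[which.max(f)]
  }, character(1))
}

#' @export
as.data.frame.kr_logo <- function(x, ...) {
  L <- ncol(x$freq)
  do.call(rbind, lapply(seq_len(L), function(j) {
    keep <- x$freq[, j] > 0
    if (!any(keep))
      return(data.frame(column = j, residue = NA_character_, freq = 0,
                        info = x$info[j], height = 0,
                        gap_fraction = x$gap_fraction[j]))
    data.frame(column = j, residue = AA20[keep], freq = x$freq[keep, j],
               info = x$info[j], height = x$heights[keep, j],
               gap_fraction = x$gap_fraction[j])
  }))
}

#' @export
plot.kr_logo <- function(x, columns = seq_len(ncol(x$freq)), ...) {
  L <- length(columns)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, log2(20)),
                 xlab = "column", ylab = "bits", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(L), labels = columns)
  for (k in seq_len(L)) {
    j <- columns[k]
    h <- x$heights[, j]
    ord <- order(h)
    y0 <- 0
    for (r in ord[h[ord] > 0]) {
      graphics::text(k, y0 + h[r] / 2, AA20[r],
                     cex = 0.4 + 2.2 * h[r] / log2(20))
      y0 <- y0 + h[r]
    }
  }
  invisible(x)
}

#' Group-wise logos over anchored records
#'
#' Anchors every record onto the reference columns and computes one logo
#' per group (by default per module type and product label), enabling
#' re-derivation of the fingerprint motifs from any labelled dataset.
#'
#' @param records A \code{\link{kr_dataset}}.
#' @param profile A \code{\link{kr_reference_profile}}.
#' @param group_by Record fields to group on (module type is derived from
#'   the domain string when requested).
#' @param ... Passed to \code{\link{anchor_map}}.
#' @return Named list of \code{\link{kr_logo}} objects; empty groups are
#'   skipped with a warning, unalignable records are dropped with a
#'   warning.
#' @export
group_logos <- function(records, profile = kr_reference_profile(),
                        group_by = c("module_type", "product_label"), ...) {
  mat <- kr_anchor_matrix(records, profile, ...)
  ok <- rownames(mat)
  recs <- records[match(ok, records$id), , drop = FALSE]
  keys <- lapply(group_by, function(g) {
    if (g == "module_type") .classify_modules(recs$module_domains)
    else recs[[g]]
  })
  key <- do.call(paste, c(keys, sep = "."))
  out <- list()
  for (k in unique(key)) {
    rows <- mat[key == k, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("empty group ", k, " skipped", call. = FALSE)
      next
    }
    out[[k]] <- kr_logo(rows)
  }
  out
}

#' Anchored residue matrix for a set of records
#'
#' @inheritParams group_logos
#' @return Character matrix (records x reference columns); records that
#'   fail to align are omitted with a warning.
#' @export
kr_anchor_matrix <- function(records, profile = kr_reference_profile(),
                             ...) {
  maps <- list(); failed <- character(0)
  sc <- .reference_scores(records$sequence, profile)
  best_ref <- colnames(sc)[max.col(sc, ties.method = "first")]
  for (i in seq_len(nrow(records))) {
    anc <- tryCatch(anchor_map(records[i, , drop = FALSE], profile,
                               reference_id = best_ref[i], ...),
                    error = function(e) NULL)
    if (is.null(anc)) failed <- c(failed, records$id[i])
    else maps[[records$id[i]]] <- anc$map
  }
  if (length(failed) > 0L)
    warning("unalignable records omitted: ",
            paste(failed, collapse = ","), call. = FALSE)
  if (length(maps) == 0L) stop("no alignable records", call. = FALSE)
  do.call(rbind, maps)
}
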