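# Phylogenetic fallback: Jukes-Cantor protein distances, Neighbor-Joining
# trees over anchored columns, and clade-based stereotype assignment.

#' Observed proportion of differing sites (p-distance)
#'
#' Pairwise-deletion p-distance between two aligned rows: sites with a gap
#' in either row are excluded, and the distance is the fraction of the
#' remaining sites at which the rows differ.
#'
#' @param a,b Aligned rows: equal-length character vectors or strings
#'   from the same column space (\code{-} marks a gap).
#' @return A proportion in [0, 1).
#' @examples
#' kr_p_distance("ACDEFGHIKL", "ACDEFGHIKV")  # 0.1
#' @export
kr_p_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b))
    stop("rows must come from the same column space", call. = FALSE)
  ok <- !.is_gap(a) & !.is_gap(b)
  if (!any(ok)) stop("no comparable (gap-free) sites", call. = FALSE)
  mean(a[ok] != b[ok])
}

#' Jukes-Cantor correction for amino-acid distances
#'
#' Converts an observed proportion of differences into an evolutionary
#' distance under the 20-letter Jukes-Cantor model:
#' \deqn{d = -\frac{19}{20}\,\ln\!\left(1 - \frac{20}{19}\,p\right)}
#' The correction is strictly increasing and never smaller than p.  At
#' p >= 19/20 the model saturates; callers may substitute a cap via
#' the \code{cap} argument instead of erroring.
#'
#' @param p Observed proportion(s) of differing sites.
#' @param cap Optional distance substituted for saturated pairs; default
#'   \code{NULL} raises an error on saturation.
#' @return Corrected distance(s).
#' @examples
#' jc_correct(0)    # 0
#' jc_correct(0.1)  # ~0.10566
#' @export
jc_correct <- function(p, cap = NULL) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  sat <- p >= 19 / 20
  if (any(sat) && is.null(cap))
    stop("saturated p-distance (p >= 19/20); supply a cap", call. = FALSE)
  d <- numeric(length(p))
  d[!sat] <- -(19 / 20) * log(1 - (20 / 19) * p[!sat])
  if (any(sat)) d[sat] <- cap
  d
}

#' Distance matrix over anchored rows
#'
#' Computes all pairwise p-distances (pairwise deletion) and optionally
#' applies the Jukes-Cantor correction.
#'
#' @param rows Named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = sequences).
#' @param correction \code{"jc"} (default) or \code{"p"} (none).
#' @param cap Saturation cap passed to \code{\link{jc_correct}}.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
kr_distance_matrix <- function(rows, correction = c("jc", "p"), cap = NULL) {
  correction <- match.arg(correction)
  if (is.character(rows) && !is.matrix(rows)) {
    labels <- names(rows)
    if (is.null(labels)) labels <- paste0("seq", seq_along(rows))
    mat <- do.call(rbind, strsplit(rows, ""))
  } else {
    mat <- rows
    labels <- rownames(rows)
    if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(rows)))
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    p <- kr_p_distance(mat[i, ], mat[j, ])
    d[i, j] <- d[j, i] <- if (correction == "jc") jc_correct(p, cap = cap)
                          else p
  }
  d
}

#' Neighbor-Joining tree
#'
#' Standard Saitou-Nei Neighbor-Joining agglomeration (via
#' \code{ape::nj}); on an additive distance matrix the generating topology
#' and branch lengths are recovered exactly.  Negative branch lengths,
#' which NJ can produce on non-additive inputs, are clamped to zero and
#' flagged in the \code{clamped_edges} attribute.
#'
#' @param D A symmetric distance matrix (n >= 3) with labelled rows.
#' @return An \code{ape} \code{phylo} tree (unrooted).
#' @export
kr_nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) < 3L)
    stop("Neighbor-Joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  tree <- ape::nj(D)
  neg <- which(tree$edge.length < 0)
  if (length(neg) > 0L) tree$edge.length[neg] <- 0
  attr(tree, "clamped_edges") <- length(neg)
  tree
}

#' Serialize / parse newick
#'
#' Thin wrappers around \code{ape::write.tree} / \code{ape::read.tree};
#' serialize-parse-serialize is a fixed point.
#'
#' @param tree A \code{phylo} object.
#' @param text A newick string.
#' @export
kr_write_newick <- function(tree) ape::write.tree(tree)

#' @rdname kr_write_newick
#' @export
kr_read_newick <- function(text) ape::read.tree(text = text)

# tip index sets below each node of a phylo tree
.tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Assign a stereotype by clade membership
#'
#' Walks outward from the query tip through the nested clades of the
#' (unrooted) tree: every edge defines a split, and the side containing
#' the query is an enclosing clade.  The call is the majority label of the
#' smallest enclosing clade containing at least \code{min_refs} labelled
#' reference tips with label purity at least \code{min_purity}; if at the
#' smallest qualifying size two clades disagree, or no enclosing clade
#' ever qualifies, the query is \code{"unresolved"}.  The procedure only
#' depends on the splits of the tree, so it is invariant under re-rooting.
#'
#' @param tree A \code{phylo} tree containing the query tip.
#' @param query_tip Tip label of the query.
#' @param ref_labels Named character vector: reference tip label ->
#'   stereotype.
#' @param min_purity Minimum majority-label fraction (default 0.8).
#' @param min_refs Minimum number of labelled references in the clade
#'   (default 3).
#' @return A stereotype label or \code{"unresolved"}.
#' @export
clade_assign <- function(tree, query_tip, ref_labels,
                         min_purity = 0.8, min_refs = 3L) {
  if (length(ref_labels) == 0L)
    stop("no labelled reference tips", call. = FALSE)
  tips <- tree$tip.label
  qi <- match(query_tip, tips)
  if (is.na(qi)) stop("query tip not in tree", call. = FALSE)
  ref_idx <- match(names(ref_labels), tips)
  keep <- !is.na(ref_idx)
  ref_idx <- ref_idx[keep]; ref_lab <- unname(ref_labels[keep])
  if (length(ref_idx) == 0L)
    stop("no labelled reference tips present in the tree", call. = FALSE)

  n_tip <- length(tips)
  sets <- .tip_sets(tree)
  cands <- list()
  for (node in seq_along(sets)) {
    if (node == qi) next
    s <- sets[[node]]
    if (length(s) == 0L || length(s) >= n_tip) next
    side <- if (qi %in% s) s else setdiff(seq_len(n_tip), s)
    cands[[length(cands) + 1L]] <- sort(side)
  }
  cands[[length(cands) + 1L]] <- seq_len(n_tip)   # whole tree, last resort
  cands <- unique(cands)
  sizes <- vapply(cands, length, integer(1))
  for (sz in sort(unique(sizes))) {
    labels_here <- character(0)
    for (s in cands[sizes == sz]) {
      in_clade <- ref_idx %in% s
      if (sum(in_clade) < min_refs) next
      tab <- table(ref_lab[in_clade])
      purity <- max(tab) / sum(tab)
      if (purity >= min_purity)
        labels_here <- c(labels_here, names(tab)[which.max(tab)])
    }
    labels_here <- unique(labels_here)
    if (length(labels_here) == 1L) return(labels_here)
    if (length(labels_here) > 1L) return("unresolved")
  }
  "unresolved"
}
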