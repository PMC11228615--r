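# Independent oracles and shared fixtures.

# Loaded once per test run; the profile/catalog are small.
test_profile <- kr_reference_profile()
test_catalog <- kr_catalog()

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Brute-force global affine alignment score: enumerate every monotone
# edit path; a gap block of length L costs open + extend * L.
brute_force_align_score <- function(a, b, submat = blosum62,
                                    gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, sc + submat[A[i], B[j]], "M")
    if (i <= na)
      rec(i + 1L, j, sc - gap_extend - if (last == "I") 0 else gap_open, "I")
    if (j <= nb)
      rec(i, j + 1L, sc - gap_extend - if (last == "D") 0 else gap_open, "D")
  }
  rec(1L, 1L, 0, "start")
  best
}

# Independent module-typing rules: count- and rank-based formulation
# (vs the architecture-vector matching used by the implementation).
module_type_oracle <- function(domains) {
  canonical <- c("KS", "AT", "DH", "ER", "KR", "ACP")
  d <- domains[domains %in% canonical]
  counts <- table(factor(d, levels = canonical))
  if (any(counts > 1L)) return("unconventional")
  present <- names(counts)[counts == 1L]
  ranks <- match(d, canonical)
  if (is.unsorted(ranks, strictly = TRUE)) return("unconventional")
  set_eq <- function(x) setequal(present, x)
  if (set_eq(c("KS", "AT", "ACP"))) return("alpha")
  if (set_eq(c("KS", "AT", "KR", "ACP"))) return("beta")
  if (set_eq(c("KS", "AT", "DH", "KR", "ACP"))) return("gamma")
  if (set_eq(c("KS", "AT", "DH", "ER", "KR", "ACP"))) return("delta")
  "unconventional"
}

# Random additive distance matrix from a random tree with positive
# branch lengths; returns the matrix and the generating tree.
random_additive_matrix <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- stats::runif(length(tree$edge.length), 0.05, 1)
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}

# Build a KR_C query from a stereotype's default anchors plus explicit
# per-anchor overrides (strings of the anchor's width).
make_query_krc <- function(stereotype = "B1", overrides = list(),
                           profile = test_profile) {
  anchors <- profile$anchors
  chars <- strsplit(profile$sequences[[profile$primary]], "")[[1]]
  pools <- krstereo:::.kr_type_anchor_pools(stereotype)
  for (a in names(pools)) {
    i <- match(a, anchors$anchor)
    chars[seq(anchors$start[i], anchors$end[i])] <-
      vapply(pools[[a]], function(p) p[[1L]], character(1))
  }
  for (a in names(overrides)) {
    i <- match(a, anchors$anchor)
    cols <- seq(anchors$start[i], anchors$end[i])
    stopifnot(nchar(overrides[[a]]) == length(cols))
    chars[cols] <- strsplit(overrides[[a]], "")[[1]]
  }
  paste(chars[seq(profile$krc_start, profile$ncol)], collapse = "")
}

# anchor + call + predict in one step for rule-engine tests
predict_query <- function(seq, taxon = "actinobacteria", module = "beta",
                          alpha = TRUE) {
  anc <- anchor_map(seq, test_profile)
  kr_predict(call_motifs(anc, test_catalog), taxon, module, alpha)
}

# small labelled dataset writers for io tests
write_test_fasta <- function(ids, seqs, path) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
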