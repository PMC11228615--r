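# Fingerprint-motif catalog.
#
# KR domains sort into A-type (L-beta-hydroxy product), B-type
# (D-beta-hydroxy) and C-type (reduction-incompetent), with subtypes 1
# (non-epimerizing) and 2 (epimerizing) when the substrate carries an
# alpha-substituent.  The classical diagnostics are the LDD motif (B),
# the W motif (A), H (A2) and P (B2); companion motifs on the alphaDE
# helix, the alphaE-betaE loop and the alphaFG lid helix (R/Q, T/L, D,
# GM, RLXR/XLXR, terminal H) sharpen the call, and the catalytic Y/K plus
# the glycine-rich NADPH-binding site separate reduction-competent KRs
# from C-types.  Anchors are expressed as column coordinates in the
# packaged reference alignment (see kr_reference_profile).

# Column coordinates (1-based, within the 380-column reference alignment;
# columns 1-150 are the structural subdomain KR_S, 151-380 the catalytic
# subdomain KR_C).  Motif numbering follows the conventional 1-13 order
# along the KR_C sequence; motif 1 is an inert placeholder with no
# type-diagnostic residue assigned.
.kr_anchor_table <- function() {
  data.frame(
    anchor = c("motif1", "nadph_1", "nadph_2", "nadph_3", "nadph_4",
               "motif2", "motif3", "motif4", "motif5", "motif6",
               "motif7", "motif8", "motif9", "motif10", "motif11",
               "motif12", "motif13"),
    motif  = c(1L, NA, NA, NA, NA, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
               11L, 12L, 13L),
    region = c("helix_alphaB", "NADPH_site", "NADPH_site", "NADPH_site",
               "NADPH_site", "LDD_region", "helix_alphaDE", "catalytic_K",
               "position5", "loop_alphaE_betaE", "W_position",
               "H_A2_position", "catalytic_Y", "P_B2_position",
               "GM_prelid", "lid_RLXR", "lid_terminal_H"),
    start  = c(155L, 160L, 162L, 165L, 185L, 200L, 210L, 216L, 222L,
               240L, 252L, 258L, 268L, 274L, 300L, 310L, 320L),
    end    = c(155L, 160L, 162L, 165L, 185L, 202L, 210L, 216L, 222L,
               240L, 252L, 258L, 268L, 274L, 301L, 313L, 320L),
    stringsAsFactors = FALSE
  )
}

# Expected residue patterns per stereotype tag.  X matches any non-gap
# residue; "absent" (motif 11 only) is called when neither column carries
# the conserved G/M.  Tags: A/B feed the beta-stereochemistry vote, A2/B2
# mark the epimerizing subtypes, catalytic/C2/reductase/nadph feed the
# reduction-competence branch.
.kr_expected_table <- function() {
  rows <- list(
    c("motif2",  "B",         "LDD"),
    c("motif2",  "A2",        "LXX"),
    c("motif3",  "B",         "R"),
    c("motif3",  "B2",        "Q"),
    c("motif4",  "reductase", "K"),
    c("motif5",  "B",         "T"),
    c("motif5",  "A",         "L"),
    c("motif6",  "A",         "D"),
    c("motif7",  "A",         "W"),
    c("motif8",  "A2",        "H"),
    c("motif9",  "catalytic", "Y"),
    c("motif9",  "C2",        "Q"),
    c("motif10", "B2",        "P"),
    c("motif11", "reductase", "GM"),
    c("motif11", "A2",        "absent"),
    c("motif12", "B",         "RLXR"),
    c("motif12", "A",         "XLXR"),
    c("motif13", "B2",        "H"),
    c("nadph_1", "nadph",     "G"),
    c("nadph_2", "nadph",     "G"),
    c("nadph_3", "nadph",     "G"),
    c("nadph_4", "nadph",     "G")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("anchor", "tag", "pattern")
  out
}

#' Fingerprint motif catalog
#'
#' Returns the packaged catalog of fingerprint anchors: motifs 1-13 plus the
#' four-column NADPH-binding site, each with its structural region, its
#' column coordinates in the reference alignment, and the residue patterns
#' expected per stereotype (e.g. motif 2 reads \code{LDD} in B-type KRs,
#' motif 7 reads \code{W} in A-type KRs).  Motif 1 is carried as an inert
#' placeholder with no expected residues.
#'
#' @return An object of class \code{kr_catalog}: a data frame with one row
#'   per (anchor, stereotype tag) expectation, plus attributes
#'   \code{anchors} (the anchor coordinate table) and \code{anchor_names}.
#' @examples
#' cat <- kr_catalog()
#' subset(cat, anchor == "motif7")
#' @export
kr_catalog <- function() {
  anchors <- .kr_anchor_table()
  expected <- .kr_expected_table()
  stopifnot(all(expected$anchor %in% anchors$anchor))
  structure(expected,
            anchors = anchors,
            anchor_names = anchors$anchor,
            class = c("kr_catalog", "data.frame"))
}

#' @export
print.kr_catalog <- function(x, ...) {
  anchors <- attr(x, "anchors")
  cat(sprintf("KR fingerprint catalog: %d anchors (%d numbered motifs + NADPH site)\n",
              nrow(anchors), sum(!is.na(anchors$motif))))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

# Concrete anchor residues per stereotype, used both for the packaged
# synthetic reference rows and for the sequence generator.  Each entry is
# a list of per-column residue pools; single-letter pools are fixed
# residues, longer pools are sampled uniformly at generation time.
.kr_type_anchor_pools <- function(stereotype) {
  base <- switch(sub("0$", "1", stereotype),  # A0/B0/C0 share subtype-1 anchors
    A1 = list(
      motif2 = list("G", "A", "S"), motif3 = list("E"), motif4 = list("K"),
      motif5 = list("L"), motif6 = list("D"), motif7 = list("W"),
      motif8 = list("A"), motif9 = list("Y"), motif10 = list("L"),
      motif11 = list("G", "M"),
      motif12 = list(setdiff(AA20, "R"), "L", AA20, "R"),
      motif13 = list("D"),
      nadph_1 = list("G"), nadph_2 = list("G"), nadph_3 = list("G"),
      nadph_4 = list("G")),
    A2 = list(
      motif2 = list("L", setdiff(AA20, "D"), setdiff(AA20, "D")),
      motif3 = list("E"), motif4 = list("K"),
      motif5 = list("L"), motif6 = list("D"), motif7 = list("W"),
      motif8 = list("H"), motif9 = list("Y"), motif10 = list("L"),
      motif11 = list(setdiff(AA20, "G"), setdiff(AA20, "M")),
      motif12 = list(setdiff(AA20, "R"), "L", AA20, "R"),
      motif13 = list("D"),
      nadph_1 = list("G"), nadph_2 = list("G"), nadph_3 = list("G"),
      nadph_4 = list("G")),
    B1 = list(
      motif2 = list("L", "D", "D"), motif3 = list("R"), motif4 = list("K"),
      motif5 = list("T"), motif6 = list("S"), motif7 = list("G"),
      motif8 = list("A"), motif9 = list("Y"), motif10 = list("L"),
      motif11 = list("G", "M"),
      motif12 = list("R", "L", AA20, "R"),
      motif13 = list("D"),
      nadph_1 = list("G"), nadph_2 = list("G"), nadph_3 = list("G"),
      nadph_4 = list("G")),
    B2 = list(
      motif2 = list("L", "D", "D"), motif3 = list("Q"), motif4 = list("K"),
      motif5 = list("T"), motif6 = list("S"), motif7 = list("G"),
      motif8 = list("A"), motif9 = list("Y"), motif10 = list("P"),
      motif11 = list("G", "M"),
      motif12 = list("R", "L", AA20, "R"),
      motif13 = list("H"),
      nadph_1 = list("G"), nadph_2 = list("G"), nadph_3 = list("G"),
      nadph_4 = list("G")),
    C1 = list(
      motif2 = list("G", "A", "S"), motif3 = list("E"), motif4 = list("A"),
      motif5 = list("V"), motif6 = list("S"), motif7 = list("G"),
      motif8 = list("A"), motif9 = list("F"), motif10 = list("L"),
      motif11 = list("G", "M"),
      motif12 = list(setdiff(AA20, "R"), "L", AA20, "R"),
      motif13 = list("D"),
      nadph_1 = list("E"), nadph_2 = list("E"), nadph_3 = list("E"),
      nadph_4 = list("E")),
    C2 = list(
      motif2 = list("L", "D", "D"), motif3 = list("Q"), motif4 = list("K"),
      motif5 = list("T"), motif6 = list("S"), motif7 = list("G"),
      motif8 = list("A"), motif9 = list(c("Y", "Q")), motif10 = list("P"),
      motif11 = list("G", "M"),
      motif12 = list("R", "L", AA20, "R"),
      motif13 = list("H"),
      nadph_1 = list("E"), nadph_2 = list("E"), nadph_3 = list("E"),
      nadph_4 = list("E")),
    stop(sprintf("unknown stereotype '%s'", stereotype), call. = FALSE)
  )
  base
}

.kr_stereotypes <- c("A0","A1","A2","B0","B1","B2","C0","C1","C2")
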