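# Stratified rule engine: motif calls -> stereochemistry prediction.
#
# Decision order:
#   (i)  reduction-competence branch: a KR with neither the catalytic Y
#        nor its Q surrogate, or with a mutated NADPH-binding site, is
#        C-type regardless of stratum (beta-stereo motifs are meaningless
#        without reduction).
#   (ii) actinobacterial beta-modules: weighted vote between the B motifs
#        {full LDD(2), R(3), T(5), RLXR(12)} and the A motifs {W(7), L(5),
#        D(6), XLXR(12) with non-R first position}; margin >= 2 gives high
#        confidence, 1 moderate, tie is ambiguous.  Epimerizing subtype
#        only when the substrate is alpha-substituted: A2 on H(8) or
#        (L-only LDD + missing GM(11)); B2 on P(10) or terminal H(13).
#   (iii) non-actinobacterial KRs: full LDD -> B (high); else W -> A
#        (moderate); subtype is not predictable (H/P are not conserved
#        outside actinobacteria).
#   (iv) actinobacterial gamma/delta-modules: the second D of the LDD
#        motif -> B (low; moderate when T(5) concurs); otherwise
#        ambiguous; subtype is not predictable and phylogenetic placement
#        is recommended.

.KR_CONF_LEVELS <- c("not_applicable", "low", "moderate", "high")

#' Predict KR stereochemistry from motif calls
#'
#' @param calls A \code{kr_calls} table from \code{\link{call_motifs}}.
#' @param taxon_group One of \code{"actinobacteria"},
#'   \code{"myxobacteria"}, \code{"cyanobacteria"}, \code{"other"}.
#' @param module_type One of \code{"beta"}, \code{"gamma"},
#'   \code{"delta"}, \code{"unconventional"} (an alpha-module has no KR
#'   and is an error).
#' @param alpha_substituted Does the substrate carry an alpha-substituent?
#'   Subtype 1/2 is only defined when it does.  \code{NA} defaults to
#'   \code{TRUE} with a warning.
#' @param nadph_min_fraction Threshold for NADPH-site integrity
#'   (see \code{\link{nadph_site_intact}}).
#' @return A \code{kr_prediction} list: \code{beta_stereo} (A/B/C/
#'   ambiguous), \code{alpha_subtype} (\code{"1"}, \code{"2"},
#'   \code{"none"}, \code{"unpredictable"}), \code{combined_label},
#'   \code{confidence}, \code{evidence} data frame and
#'   \code{applicability_note}.
#' @export
kr_predict <- function(calls, taxon_group, module_type,
                       alpha_substituted = NA,
                       nadph_min_fraction = 0.75) {
  if (identical(as.character(module_type), "alpha"))
    stop("no KR in an alpha-module", call. = FALSE)
  module_type <- as.character(module_type)
  if (is.na(alpha_substituted)) {
    warning("alpha_substituted unknown; assuming TRUE", call. = FALSE)
    alpha_substituted <- TRUE
  }
  actino <- identical(taxon_group, "actinobacteria")
  ev <- list()
  note <- ""
  add_ev <- function(anchor, obs, contribution) {
    ev[[length(ev) + 1L]] <<- data.frame(
      anchor = anchor, observation = obs, contribution = contribution,
      stringsAsFactors = FALSE)
  }
  obs_at <- function(anchor) calls$observed[match(anchor, calls$anchor)]
  grade <- attr(calls, "ldd_grade")

  ## (i) reduction-competence branch
  y_present <- .has_tag(calls, "motif9", "catalytic")
  q_present <- .has_tag(calls, "motif9", "C2")
  nad <- calls[grepl("^nadph_", calls$anchor), , drop = FALSE]
  nad_matched <- vapply(nad$anchor, function(a) .has_tag(nad, a, "nadph"),
                        logical(1))
  nad_low <- mean(nad$status == "gap") >= 0.5
  nad_intact <- !nad_low && mean(nad_matched) >= nadph_min_fraction

  c_type <- FALSE
  c_signals <- 0L
  if (!y_present && !q_present) {
    c_type <- TRUE; c_signals <- c_signals + 1L
    add_ev("motif9", obs_at("motif9"), "catalytic Y absent (not Q) -> C")
  }
  if ((y_present || q_present) && !nad_intact) c_type <- TRUE
  if (!nad_intact) {
    c_signals <- c_signals + 1L
    add_ev("nadph_site", paste(nad$observed, collapse = "/"),
           sprintf("NADPH-binding site not intact (%.2f matching) -> C",
                   mean(nad_matched)))
  }

  if (c_type) {
    subtype <- "unpredictable"
    if (actino && module_type == "beta") {
      if (!alpha_substituted) {
        subtype <- "none"
      } else {
        markers2 <- .has_tag(calls, "motif8", "A2") ||
          .has_tag(calls, "motif10", "B2") || .has_tag(calls, "motif13", "B2")
        k4 <- .has_tag(calls, "motif4", "reductase")
        if (markers2 && k4) {
          subtype <- "2"
          add_ev("motif4", obs_at("motif4"),
                 "conserved K with subtype-2 markers -> C2")
        } else subtype <- "1"
      }
    }
    conf <- if (c_signals >= 2L) "high" else "moderate"
    return(.kr_prediction("C", subtype, conf, ev, note, taxon_group,
                          module_type, calls))
  }

  ## strata for reduction-competent KRs
  if (actino && module_type == "beta") {
    b_votes <- 0L; a_votes <- 0L
    if (.has_tag(calls, "motif2", "B")) {
      b_votes <- b_votes + 1L; add_ev("motif2", obs_at("motif2"), "full LDD -> B")
    }
    if (.has_tag(calls, "motif3", "B")) {
      b_votes <- b_votes + 1L; add_ev("motif3", obs_at("motif3"), "R -> B")
    }
    if (.has_tag(calls, "motif5", "B")) {
      b_votes <- b_votes + 1L; add_ev("motif5", obs_at("motif5"), "T -> B")
    }
    if (.has_tag(calls, "motif12", "B")) {
      b_votes <- b_votes + 1L; add_ev("motif12", obs_at("motif12"), "RLXR -> B")
    }
    if (.has_tag(calls, "motif7", "A")) {
      a_votes <- a_votes + 1L; add_ev("motif7", obs_at("motif7"), "W -> A")
    }
    if (.has_tag(calls, "motif5", "A")) {
      a_votes <- a_votes + 1L; add_ev("motif5", obs_at("motif5"), "L -> A")
    }
    if (.has_tag(calls, "motif6", "A")) {
      a_votes <- a_votes + 1L; add_ev("motif6", obs_at("motif6"), "D -> A")
    }
    if (.has_tag(calls, "motif12", "A") && !.has_tag(calls, "motif12", "B")) {
      a_votes <- a_votes + 1L
      add_ev("motif12", obs_at("motif12"), "XLXR (non-R first) -> A")
    }
    margin <- abs(b_votes - a_votes)
    if (b_votes == a_votes) {
      note <- "A and B evidence balanced; consider phylogenetic placement"
      return(.kr_prediction("ambiguous", "unpredictable", "not_applicable",
                            ev, note, taxon_group, module_type, calls))
    }
    type <- if (b_votes > a_votes) "B" else "A"
    conf <- if (margin >= 2L) "high" else "moderate"
    subtype <- if (!alpha_substituted) "none" else {
      if (type == "A") {
        a2 <- .has_tag(calls, "motif8", "A2") ||
          (grade == "l_only" && .has_tag(calls, "motif11", "A2"))
        if (a2) {
          add_ev("motif8", obs_at("motif8"), "A2 markers -> subtype 2")
          "2"
        } else "1"
      } else {
        b2 <- .has_tag(calls, "motif10", "B2") || .has_tag(calls, "motif13", "B2")
        if (b2) {
          add_ev("motif10", obs_at("motif10"), "B2 markers -> subtype 2")
          "2"
        } else "1"
      }
    }
    return(.kr_prediction(type, subtype, conf, ev, note, taxon_group,
                          module_type, calls))
  }

  if (!actino) {
    note <- "non-actinobacterial KR: alpha-subtype motifs (H/P) are not conserved"
    if (.has_tag(calls, "motif2", "B")) {
      add_ev("motif2", obs_at("motif2"), "full LDD -> B")
      return(.kr_prediction("B", "unpredictable", "high", ev, note,
                            taxon_group, module_type, calls))
    }
    if (.has_tag(calls, "motif7", "A")) {
      add_ev("motif7", obs_at("motif7"), "W (no LDD) -> A, moderate")
      return(.kr_prediction("A", "unpredictable", "moderate", ev, note,
                            taxon_group, module_type, calls))
    }
    return(.kr_prediction("ambiguous", "unpredictable", "not_applicable",
                          ev, note, taxon_group, module_type, calls))
  }

  ## actinobacterial gamma/delta (and unconventional modules with a KR)
  note <- paste("DH-associated KR: motif-based call is tentative;",
                "phylogenetic placement of KR_C recommended")
  if (grade %in% c("full", "second_d")) {
    add_ev("motif2", obs_at("motif2"), "second D of LDD present -> B (tentative)")
    conf <- "low"
    if (.has_tag(calls, "motif5", "B")) {
      conf <- "moderate"
      add_ev("motif5", obs_at("motif5"), "T concurs -> B")
    }
    return(.kr_prediction("B", "unpredictable", conf, ev, note,
                          taxon_group, module_type, calls))
  }
  .kr_prediction("ambiguous", "unpredictable", "not_applicable", ev, note,
                 taxon_group, module_type, calls)
}

.kr_prediction <- function(type, subtype, confidence, ev, note,
                           taxon_group, module_type, calls) {
  label <- if (type == "ambiguous") "ambiguous"
    else switch(subtype,
                "1" = paste0(type, "1"),
                "2" = paste0(type, "2"),
                "none" = paste0(type, "0"),
                type)
  structure(list(
    beta_stereo = type, alpha_subtype = subtype, combined_label = label,
    confidence = confidence,
    evidence = if (length(ev)) do.call(rbind, ev) else
      data.frame(anchor = character(0), observation = character(0),
                 contribution = character(0)),
    applicability_note = note,
    taxon_group = taxon_group, module_type = module_type,
    id = attr(calls, "id")), class = "kr_prediction")
}

#' @export
print.kr_prediction <- function(x, ...) {
  cat(sprintf("KR prediction for '%s': %s (beta-stereo %s, subtype %s), confidence %s\n",
              x$id, x$combined_label, x$beta_stereo, x$alpha_subtype,
              x$confidence))
  if (nzchar(x$applicability_note))
    cat("  note:", x$applicability_note, "\n")
  if (nrow(x$evidence)) {
    cat("  evidence:\n")
    for (i in seq_len(nrow(x$evidence)))
      cat(sprintf("    %-10s %-6s %s\n", x$evidence$anchor[i],
                  x$evidence$observation[i], x$evidence$contribution[i]))
  }
  invisible(x)
}

#' Batch prediction over a KR dataset
#'
#' Anchors every record, calls its motifs and runs the stratified rule
#' engine.  Records that fail to align (coverage below threshold) are
#' reported as failures, not errors.  When ground-truth product labels are
#' present, per-label criterion-satisfaction rates and a confusion table
#' are attached.
#'
#' @param records A \code{\link{kr_dataset}} data frame.
#' @param profile A \code{\link{kr_reference_profile}}.
#' @param catalog A \code{\link{kr_catalog}}.
#' @param min_coverage Passed to \code{\link{anchor_map}}.
#' @return A \code{kr_predictions} data frame (one row per record:
#'   \code{id}, \code{module_type}, \code{taxon_group},
#'   \code{combined_label}, \code{beta_stereo}, \code{alpha_subtype},
#'   \code{confidence}, \code{note}, \code{aligned}), with attributes
#'   \code{satisfaction} (per-label exact-label recovery rates) and
#'   \code{confusion} when labels are available.
#' @export
kr_predict_batch <- function(records, profile = kr_reference_profile(),
                             catalog = kr_catalog(), min_coverage = 0.5) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  sc <- .reference_scores(records$sequence, profile)
  best_ref <- colnames(sc)[max.col(sc, ties.method = "first")]
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    mtype <- .classify_modules(rec$module_domains)
    base <- data.frame(id = rec$id, module_type = mtype,
                       taxon_group = rec$taxon_group,
                       combined_label = NA_character_,
                       beta_stereo = NA_character_,
                       alpha_subtype = NA_character_,
                       confidence = NA_character_, note = "",
                       aligned = FALSE, stringsAsFactors = FALSE)
    if (mtype == "alpha") {
      base$note <- "no KR in alpha-module"
      return(base)
    }
    anc <- tryCatch(anchor_map(rec, profile, min_coverage = min_coverage,
                               reference_id = best_ref[i]),
                    error = function(e) e)
    if (inherits(anc, "error")) {
      base$note <- conditionMessage(anc)
      return(base)
    }
    calls <- call_motifs(anc, catalog)
    alpha_sub <- if ("alpha_substituted" %in% names(rec))
      rec$alpha_substituted else NA
    pred <- kr_predict(calls, rec$taxon_group, mtype, alpha_sub)
    base$combined_label <- pred$combined_label
    base$beta_stereo <- pred$beta_stereo
    base$alpha_subtype <- pred$alpha_subtype
    base$confidence <- pred$confidence
    base$note <- pred$applicability_note
    base$aligned <- TRUE
    base
  })
  out <- do.call(rbind, rows)

  if ("product_label" %in% names(records) &&
      any(!is.na(records$product_label) & records$product_label != "unknown")) {
    truth <- records$product_label
    known <- !is.na(truth) & truth != "unknown" & out$aligned
    sat <- tapply(out$combined_label[known] == truth[known], truth[known],
                  mean)
    conf <- table(truth = truth[known], predicted = out$combined_label[known])
    attr(out, "satisfaction") <- sat
    attr(out, "confusion") <- conf
  }
  class(out) <- c("kr_predictions", "data.frame")
  out
}

#' @export
print.kr_predictions <- function(x, ...) {
  cat(sprintf("KR predictions: %d records (%d aligned)\n", nrow(x),
              sum(x$aligned)))
  print(as.data.frame(x)[, c("id", "module_type", "taxon_group",
                             "combined_label", "confidence")],
        row.names = FALSE, ...)
  sat <- attr(x, "satisfaction")
  if (!is.null(sat)) {
    cat("per-label recovery of ground truth:\n")
    print(round(sat, 3))
  }
  invisible(x)
}
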