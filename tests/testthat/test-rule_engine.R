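test_that("canonical motif constellations give the textbook calls", {
  # full B constellation: LDD, R, T, RLXR, catalytic Y/K, intact NADPH
  p <- predict_query(make_query_krc("B1"))
  expect_equal(p$combined_label, "B1")
  expect_equal(p$confidence, "high")

  # A2: W, H, L-only LDD, missing GM
  p <- predict_query(make_query_krc("A2"))
  expect_equal(p$combined_label, "A2")
  expect_equal(p$confidence, "high")

  # C2: catalytic Y retained but NADPH site mutated; subtype-2 markers + K
  p <- predict_query(make_query_krc("C2"))
  expect_equal(p$combined_label, "C2")
  expect_equal(p$beta_stereo, "C")

  # C1: no catalytic Y and mutated NADPH site
  p <- predict_query(make_query_krc("C1"))
  expect_equal(p$combined_label, "C1")
  expect_equal(p$confidence, "high")
})

test_that("non-actinobacterial KRs get type but never a subtype", {
  p <- predict_query(make_query_krc("B2"), taxon = "myxobacteria")
  expect_equal(p$beta_stereo, "B")
  expect_equal(p$alpha_subtype, "unpredictable")
  expect_equal(p$combined_label, "B")

  p2 <- predict_query(make_query_krc("A1"), taxon = "cyanobacteria")
  expect_equal(p2$beta_stereo, "A")
  expect_equal(p2$confidence, "moderate")  # W without LDD: moderate only

  # scope guard across strata and types
  for (tx in c("myxobacteria", "cyanobacteria", "other"))
    for (ty in c("A1", "A2", "B1", "B2"))
      expect_false(predict_query(make_query_krc(ty), taxon = tx)$alpha_subtype
                   %in% c("1", "2"), info = paste(tx, ty))
})

test_that("DH-associated KRs are called only through the second D", {
  p <- predict_query(make_query_krc("B1"), module = "gamma")
  expect_equal(p$beta_stereo, "B")
  expect_equal(p$confidence, "moderate")   # second D plus concurring T
  expect_equal(p$alpha_subtype, "unpredictable")
  expect_match(p$applicability_note, "[Pp]hylogenetic")

  # second D only, no T
  q <- make_query_krc("B1", overrides = list(motif5 = "V"))
  p2 <- predict_query(q, module = "gamma")
  expect_equal(p2$beta_stereo, "B")
  expect_equal(p2$confidence, "low")

  # A-type constellation in a gamma module stays ambiguous
  p3 <- predict_query(make_query_krc("A1"), module = "gamma")
  expect_equal(p3$beta_stereo, "ambiguous")
})

test_that("conflicting LDD and W evidence is ambiguous", {
  q <- make_query_krc("B1", overrides = list(
    motif7 = "W", motif3 = "E", motif5 = "V", motif6 = "S",
    motif12 = "ALSA"))
  p <- predict_query(q)
  expect_equal(p$beta_stereo, "ambiguous")
  expect_equal(p$confidence, "not_applicable")
})

test_that("adding concordant votes never flips the type or drops confidence", {
  conf_rank <- function(x) match(x, c("not_applicable", "low", "moderate",
                                      "high"))
  base <- list(motif7 = "W", motif3 = "E", motif5 = "V", motif6 = "S",
               motif12 = "ALSA")
  p0 <- predict_query(make_query_krc("B1", base))      # tie
  upgrades <- list(list(motif5 = "T"),                  # +1 B vote
                   list(motif5 = "T", motif3 = "R"),    # +2 B votes
                   list(motif5 = "T", motif3 = "R",
                        motif12 = "RLAR"))              # +3 B votes
  last_rank <- conf_rank(p0$confidence)
  for (up in upgrades) {
    ov <- modifyList(base, up)
    p <- predict_query(make_query_krc("B1", ov))
    expect_equal(p$beta_stereo, "B")
    expect_gte(conf_rank(p$confidence), last_rank)
    last_rank <- conf_rank(p$confidence)
  }
})

test_that("alpha-substitution gates the subtype digit", {
  anc <- anchor_map(make_query_krc("B1"), test_profile)
  calls <- call_motifs(anc, test_catalog)
  p0 <- kr_predict(calls, "actinobacteria", "beta", alpha_substituted = FALSE)
  expect_equal(p0$combined_label, "B0")
  expect_warning(
    pNA <- kr_predict(calls, "actinobacteria", "beta",
                      alpha_substituted = NA),
    "assuming TRUE")
  expect_equal(pNA$combined_label, "B1")
})

test_that("alpha-modules are rejected and predictions are deterministic", {
  anc <- anchor_map(make_query_krc("A1"), test_profile)
  calls <- call_motifs(anc, test_catalog)
  expect_error(kr_predict(calls, "actinobacteria", "alpha", TRUE), "alpha")
  p1 <- kr_predict(calls, "actinobacteria", "beta", TRUE)
  p2 <- kr_predict(calls, "actinobacteria", "beta", TRUE)
  expect_equal(p1[names(p1) != "evidence"], p2[names(p2) != "evidence"])
  expect_equal(p1$evidence, p2$evidence)
})

test_that("batch prediction recovers noise-free labels and flags failures", {
  labs <- c("A1", "A2", "B1", "B2", "C1")
  recs <- do.call(rbind, lapply(seq_along(labs), function(i)
    as.data.frame(kr_synth(labs[i], 20, seed = 100 + i))))
  recs <- kr_dataset(recs)
  pred <- kr_predict_batch(recs)
  expect_equal(kr_label_recovery(pred, recs), 1.0)
  sat <- attr(pred, "satisfaction")
  expect_true(all(sat == 1))

  set.seed(9)
  pep <- kr_dataset(data.frame(
    id = "pep1",
    sequence = paste(sample(krstereo:::AA20, 40, TRUE), collapse = "")))
  pb <- kr_predict_batch(pep)
  expect_false(pb$aligned)
  expect_true(is.na(pb$combined_label))
  expect_match(pb$note, "unalignable")
})
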