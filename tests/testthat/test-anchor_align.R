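test_that("identity alignment scores the diagonal and covers everything", {
  al <- global_align("LDD", "LDD")
  expect_equal(al$score, blosum62["L", "L"] + 2 * blosum62["D", "D"])
  expect_equal(al$query_aligned, "LDD")

  anc <- anchor_map(test_profile$sequences[[test_profile$primary]],
                    test_profile)
  expect_equal(anc$coverage, 1.0)
  expect_equal(paste(anc$map, collapse = ""),
               test_profile$sequences[[test_profile$primary]])
})

test_that("affine-gap optimum matches exhaustive enumeration", {
  expect_equal(global_align("LD", "LDD")$score,
               brute_force_align_score("LD", "LDD"))
  set.seed(42)
  alpha <- c("A", "R", "N", "D")
  for (k in 1:40) {
    a <- paste(sample(alpha, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, brute_force_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric and empty input errors", {
  expect_equal(global_align("MKWV", "MKV")$score,
               global_align("MKV", "MKWV")$score)
  expect_error(global_align("", "MKV"), "empty")
})

test_that("anchor_map reads mutated anchor regions faithfully", {
  anchors <- test_profile$anchors
  i <- match("motif2", anchors$anchor)
  chars <- strsplit(test_profile$sequences[[test_profile$primary]], "")[[1]]
  chars[seq(anchors$start[i], anchors$end[i])] <- c("A", "A", "A")
  anc <- anchor_map(paste(chars, collapse = ""), test_profile,
                    reference_id = test_profile$primary)
  expect_equal(paste(anc$map[seq(anchors$start[i], anchors$end[i])],
                     collapse = ""), "AAA")
  # every other anchor is unchanged
  for (j in seq_len(nrow(anchors))) {
    if (j == i) next
    cols <- seq(anchors$start[j], anchors$end[j])
    expect_equal(anc$map[cols], chars[cols])
  }
})

test_that("a short random peptide is rejected as unalignable", {
  set.seed(5)
  pep <- paste(sample(krstereo:::AA20, 50, TRUE), collapse = "")
  expect_error(anchor_map(pep, test_profile), "unalignable")
})

test_that("anchors are invariant to flanking linker residues", {
  set.seed(8)
  s <- kr_synth("A2", 1, seed = 31, subdomain = "full")
  anc0 <- anchor_map(s, test_profile)
  flank_l <- paste(sample(krstereo:::AA20, 30, TRUE), collapse = "")
  flank_r <- paste(sample(krstereo:::AA20, 25, TRUE), collapse = "")
  anc1 <- anchor_map(paste0(flank_l, s$sequence, flank_r), test_profile)
  anchors <- test_profile$anchors
  for (j in seq_len(nrow(anchors))) {
    cols <- seq(anchors$start[j], anchors$end[j])
    expect_equal(anc1$map[cols], anc0$map[cols], info = anchors$anchor[j])
  }
})

test_that("subdomain split recovers the construction boundary", {
  prim <- test_profile$sequences[[test_profile$primary]]
  krs_ref <- substr(prim, 1, test_profile$krc_start - 1)
  krc_mut <- kr_synth("B2", 1, seed = 12)$sequence  # KR_C only, mutated
  full <- paste0(krs_ref, krc_mut)
  sp <- split_subdomains(full, test_profile)
  expect_equal(sp$KR_S, krs_ref)
  expect_equal(sp$KR_C, krc_mut)
  expect_equal(paste0(sp$KR_S, sp$KR_C), full)
})

test_that("KR_C-only input yields an empty KR_S with a warning", {
  krc <- kr_synth("B1", 1, seed = 3)$sequence
  expect_warning(sp <- split_subdomains(krc, test_profile), "KR_C-only")
  expect_equal(sp$KR_S, "")
  expect_equal(sp$KR_C, krc)
})

test_that("anchor calls are stable under the subdomain split", {
  s <- kr_synth("A1", 1, seed = 77, subdomain = "full")
  anc_full <- anchor_map(s, test_profile)
  sp <- suppressWarnings(split_subdomains(s$sequence, test_profile))
  anc_krc <- anchor_map(sp$KR_C, test_profile)
  anchors <- test_profile$anchors
  for (j in seq_len(nrow(anchors))) {
    cols <- seq(anchors$start[j], anchors$end[j])
    expect_equal(anc_krc$map[cols], anc_full$map[cols],
                 info = anchors$anchor[j])
  }
})
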