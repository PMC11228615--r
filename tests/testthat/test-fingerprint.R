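test_that("the catalog holds 13 numbered motifs plus the NADPH site", {
  anchors <- attr(test_catalog, "anchors")
  expect_setequal(anchors$motif[!is.na(anchors$motif)], 1:13)
  expect_equal(sum(anchors$region == "NADPH_site"), 4L)
  # motif 1 is an inert placeholder: no expected residues
  expect_equal(nrow(subset(as.data.frame(test_catalog), anchor == "motif1")),
               0L)
  # headline expectations
  df <- as.data.frame(test_catalog)
  expect_equal(df$pattern[df$anchor == "motif7" & df$tag == "A"], "W")
  expect_equal(df$pattern[df$anchor == "motif2" & df$tag == "B"], "LDD")
  expect_equal(df$pattern[df$anchor == "motif12" & df$tag == "B"], "RLXR")
})

ref_calls <- function(row_id) {
  call_motifs(anchor_map(test_profile$sequences[[row_id]], test_profile,
                         reference_id = row_id),
              test_catalog)
}

tagged <- function(calls, anchor, tag) krstereo:::.has_tag(calls, anchor, tag)

test_that("reference rows carry the tags of their own stereotype", {
  musts <- list(
    B1 = list(c("motif2", "B"), c("motif3", "B"), c("motif5", "B"),
              c("motif12", "B"), c("motif4", "reductase"),
              c("motif9", "catalytic"), c("motif11", "reductase")),
    B2 = list(c("motif2", "B"), c("motif3", "B2"), c("motif10", "B2"),
              c("motif13", "B2"), c("motif9", "catalytic")),
    A1 = list(c("motif5", "A"), c("motif6", "A"), c("motif7", "A"),
              c("motif12", "A"), c("motif9", "catalytic"),
              c("motif11", "reductase")),
    A2 = list(c("motif7", "A"), c("motif8", "A2"), c("motif2", "A2"),
              c("motif11", "A2"))
  )
  for (row_id in names(test_profile$sequences)) {
    ty <- test_profile$types[[match(row_id, names(test_profile$sequences))]]
    if (!ty %in% names(musts)) next
    calls <- ref_calls(row_id)
    for (m in musts[[ty]])
      expect_true(tagged(calls, m[1], m[2]),
                  info = paste(row_id, m[1], m[2]))
  }
})

test_that("LDD and W motifs separate A- from B-type observations", {
  b <- ref_calls("REF_B1a")
  expect_true(tagged(b, "motif2", "B"))
  expect_false(tagged(b, "motif7", "A"))
  expect_equal(attr(b, "ldd_grade"), "full")

  a <- ref_calls("REF_A1a")
  expect_true(tagged(a, "motif7", "A"))
  expect_false(tagged(a, "motif2", "B"))
  expect_equal(attr(a, "ldd_grade"), "absent")

  a2 <- ref_calls("REF_A2")
  expect_equal(attr(a2, "ldd_grade"), "l_only")
})

test_that("motif calls ignore mutations outside anchor columns", {
  anchors <- test_profile$anchors
  anchor_cols <- unlist(mapply(seq, anchors$start, anchors$end,
                               SIMPLIFY = FALSE))
  chars <- strsplit(test_profile$sequences[["REF_B1a"]], "")[[1]]
  set.seed(2)
  bg <- sample(setdiff(seq(151, 380), anchor_cols), 12)
  chars[bg] <- vapply(chars[bg], krstereo:::.mutate_residue, character(1))
  mut_calls <- call_motifs(anchor_map(paste(chars, collapse = ""),
                                      test_profile,
                                      reference_id = "REF_B1a"),
                           test_catalog)
  ref <- ref_calls("REF_B1a")
  expect_equal(mut_calls$observed, ref$observed)
  expect_equal(mut_calls$tags, ref$tags)
})

test_that("an all-gap anchored query yields gap statuses", {
  fake <- structure(list(id = "gapq", map = rep("-", test_profile$ncol),
                         coverage = 0), class = "kr_anchored")
  calls <- call_motifs(fake, test_catalog)
  expect_true(all(calls$status == "gap"))
})

test_that("NADPH-site integrity follows the matching fraction", {
  anc <- anchor_map(test_profile$sequences[["REF_A1a"]], test_profile,
                    reference_id = "REF_A1a")
  expect_true(nadph_site_intact(anc, test_catalog)$intact)

  anchors <- test_profile$anchors
  nad_cols <- anchors$start[grepl("^nadph", anchors$anchor)]
  chars <- strsplit(test_profile$sequences[["REF_A1a"]], "")[[1]]
  chars[nad_cols] <- "E"   # all four glycines mutated
  anc_mut <- anchor_map(paste(chars, collapse = ""), test_profile,
                        reference_id = "REF_A1a")
  res <- nadph_site_intact(anc_mut, test_catalog)
  expect_false(res$intact)
  expect_equal(res$fraction, 0)

  chars2 <- strsplit(test_profile$sequences[["REF_A1a"]], "")[[1]]
  chars2[nad_cols[1]] <- "E"   # 3/4 intact passes the 0.75 default
  anc_one <- anchor_map(paste(chars2, collapse = ""), test_profile,
                        reference_id = "REF_A1a")
  expect_true(nadph_site_intact(anc_one, test_catalog)$intact)
})
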