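test_that("p-distance uses pairwise deletion", {
  expect_equal(kr_p_distance("ACDEFGHIKL", "ACDEFGHIKL"), 0)
  expect_equal(kr_p_distance("ACDEFGHIKL", "ACDEFGHIKV"), 0.1)
  # gaps shrink the comparable sites from 10 to 5; 1 mismatch -> 0.2
  expect_equal(kr_p_distance("ACDEF-----", "VCDEFGHIKL"), 0.2)
  expect_error(kr_p_distance("---", "AAA"), "no comparable")
  expect_error(kr_p_distance("AA", "AAA"), "column space")
})

test_that("Jukes-Cantor correction matches the closed form", {
  closed <- function(p) -(19 / 20) * log(1 - (20 / 19) * p)
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), closed(0.1), tolerance = 1e-12)
  ps <- seq(0, 0.9, by = 0.05)
  expect_equal(jc_correct(ps), closed(ps), tolerance = 1e-12)
  expect_error(jc_correct(0.95), "saturated")
  expect_equal(jc_correct(0.97, cap = 5), 5)
  # strictly increasing, and inflates relative to p
  d <- jc_correct(ps)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= ps))
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- kr_nj_tree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["c"]), (4 + 5 - 3) / 2)
  expect_error(kr_nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(77)
  for (k in 1:25) {
    gen <- random_additive_matrix(sample(4:6, 1))
    tr <- kr_nj_tree(gen$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), ape::unroot(tr))), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$D), colnames(gen$D)],
                 gen$D, tolerance = 1e-8)
  }
})

test_that("identical rows join first as a zero-length cherry", {
  rows <- c(x1 = "ACDEFGHIKL", x2 = "ACDEFGHIKL", y = "VWYEFGHIKL",
            z = "ACDEFWYWYW")
  D <- kr_distance_matrix(rows, correction = "p")
  expect_equal(D["x1", "x2"], 0)
  expect_true(isSymmetric(D))
  tr <- kr_nj_tree(D)
  cheries <- ape::cophenetic.phylo(tr)
  expect_equal(cheries["x1", "x2"], 0)
})

test_that("newick serialization round-trips to a fixed point", {
  set.seed(3)
  tr <- ape::rtree(7)
  nwk1 <- kr_write_newick(tr)
  nwk2 <- kr_write_newick(kr_read_newick(nwk1))
  expect_identical(nwk1, nwk2)
})

clade_tree <- function(nwk) ape::read.tree(text = nwk)

test_that("clade assignment follows the smallest pure enclosing clade", {
  refs <- c(a1 = "A1", a2 = "A1", a3 = "A1",
            b1 = "B1", b2 = "B1", b3 = "B1")
  tr <- clade_tree("(((q:1,a1:1):1,(a2:1,a3:1):1):1,(b1:1,(b2:1,b3:1):1):2);")
  expect_equal(clade_assign(tr, "q", refs), "A1")

  # query on the edge separating two pure clades: conflicting smallest
  # clades -> unresolved
  tr2 <- clade_tree("((a1:1,(a2:1,a3:1):1):1,q:1,(b1:1,(b2:1,b3:1):1):1);")
  expect_equal(clade_assign(tr2, "q", refs), "unresolved")

  # all references share one label: that label regardless of placement
  refsA <- setNames(rep("A2", 3), c("r1", "r2", "r3"))
  tr3 <- clade_tree("(q:1,r1:1,(r2:1,r3:1):1);")
  expect_equal(clade_assign(tr3, "q", refsA), "A2")

  expect_error(clade_assign(tr3, "q", character(0)), "no labelled")
  expect_error(clade_assign(tr3, "nope", refsA), "not in tree")
})

test_that("clade assignment is invariant under re-rooting", {
  refs <- c(a1 = "A1", a2 = "A1", a3 = "A1",
            b1 = "B1", b2 = "B1", b3 = "B1")
  tr <- clade_tree("(((q:1,a1:1):1,(a2:1,a3:1):1):1,(b1:1,(b2:1,b3:1):1):2);")
  for (og in c("b2", "a2", "q"))
    expect_equal(clade_assign(ape::root(tr, outgroup = og), "q", refs),
                 "A1", info = og)
})

test_that("anchored synthetic stereotype groups form assignable clades", {
  mk <- function(lab, n, seed) {
    s <- kr_synth(lab, n, seed = seed)
    s$id <- paste0(lab, "_", seq_len(n))
    s
  }
  recs <- kr_dataset(rbind(as.data.frame(mk("A1", 4, 21)),
                           as.data.frame(mk("B1", 4, 22)),
                           as.data.frame(mk("C1", 4, 23))))
  mat <- kr_anchor_matrix(recs, test_profile)
  D <- kr_distance_matrix(mat, correction = "jc", cap = 5)
  tr <- kr_nj_tree(D)
  labels <- setNames(sub("_\\d+$", "", rownames(mat)), rownames(mat))
  for (q in rownames(mat)) {
    got <- clade_assign(tr, q, labels[names(labels) != q])
    expect_equal(got, unname(labels[q]), info = q)
  }
})
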