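test_that("Poisson-corrected distances match closed forms", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  aln <- vapply(aln, function(x) paste(rep(x, 4), collapse = ""),
                character(1))  # 40 columns (>= 30 shared)
  expect_equal(protein_distance_matrix(aln)["a", "b"], 0)

  # p = 0.1 over 40 columns -> d = -ln(0.9)
  s1 <- paste(rep("A", 40), collapse = "")
  s2 <- paste(c(rep("C", 4), rep("A", 36)), collapse = "")
  d <- protein_distance_matrix(c(x = s1, y = s2))
  expect_equal(d["x", "y"], -log(1 - 0.1), tolerance = 1e-12)

  gap_only <- c(u = paste(c(rep("A", 20), rep("-", 20)), collapse = ""),
                v = paste(c(rep("-", 20), rep("A", 20)), collapse = ""))
  expect_error(protein_distance_matrix(gap_only), "non-gap")
})

test_that("NJ recovers three-taxon branch lengths in closed form", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2,
                              dimnames = list(c("a","b"), c("a","b")))),
               "3 taxa")
  dbad <- d; dbad[1, 2] <- 0.31
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ recovers the generating topology from additive distances", {
  for (s in 1:5) {
    set.seed(900 + s)
    tr <- ape::rtree(8)
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
    # label order invariance
    perm <- sample(rownames(D))
    nj2 <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(nj2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap saturates on well-separated clades and is seeded", {
  base1 <- random_protein(60, seed = 31)
  base2 <- random_protein(60, seed = 32)
  tweak <- function(s, at) {
    v <- strsplit(s, "")[[1]]; v[at] <- "W"; paste(v, collapse = "")
  }
  aln <- c(a1 = tweak(base1, 1), a2 = tweak(base1, 2),
           b1 = tweak(base2, 1), b2 = tweak(base2, 2))
  bs <- bootstrap_support(aln, n_reps = 100, seed = 4)
  expect_true(all(bs$node.label == 100))
  bs2 <- bootstrap_support(aln, n_reps = 100, seed = 4)
  expect_identical(bs$node.label, bs2$node.label)
  bs1 <- bootstrap_support(aln, n_reps = 1, seed = 4)
  expect_true(all(bs1$node.label %in% c(0, 100)))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("LCA reconciliation labels duplications and speciations", {
  st <- ape::read.tree(text = "(A:1,B:1)AB;")
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  sm <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  rec <- reconcile_lca(gt, st, sm)
  ev <- rec$events$event[rec$events$event != "leaf"]
  expect_equal(sum(ev == "duplication"), 1)
  expect_equal(sum(ev == "speciation"), 2)
  expect_equal(mrca_copy_count(rec, "AB"), 2)

  gt2 <- ape::read.tree(text = "((a1:1,a2:1):1,b1:2);")
  rec2 <- reconcile_lca(gt2, st, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(sum(rec2$events$event == "duplication"), 1)
  expect_equal(mrca_copy_count(rec2, "AB"), 1)

  # congruent single-copy gene tree: no duplications, count 1
  st4 <- ape::read.tree(text = "((A:1,B:1)AB:1,(C:1,D:1)CD:1)ABCD;")
  gt4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  sm4 <- c(a = "A", b = "B", c = "C", d = "D")
  rec4 <- reconcile_lca(gt4, st4, sm4)
  expect_equal(sum(rec4$events$event == "duplication"), 0)
  for (lbl in c("AB", "CD", "ABCD"))
    expect_equal(mrca_copy_count(rec4, lbl), 1)
  expect_error(mrca_copy_count(rec4, "A"), "leaf")
  expect_error(reconcile_lca(gt4, st4, c(sm4[-1], z = "Z")), "missing")
})

test_that("a subspecies toy history gives six copies at their split", {
  # six ortholog pairs between two rice subspecies; lineage-specific
  # tandem gains inside three of the clades do not change the ancestral
  # count at the subspecies divergence
  st <- ape::read.tree(text = "(indica:1,japonica:1)IJ;")
  gt <- ape::read.tree(text = paste0(
    "((i1:1,j1:1):1,((((i2a:0.2,i2b:0.2):0.8,j2:1):1,",
    "((i3:1,j3:1):1,(i4:1,(j4a:0.2,j4b:0.2):0.8):1):0.5):0.5,",
    "((i5:1,j5:1):1,((i6a:0.2,i6b:0.2):0.8,j6:1):1):0.5):0.5);"))
  sm <- setNames(ifelse(grepl("^i", gt$tip.label), "indica", "japonica"),
                 gt$tip.label)
  rec <- reconcile_lca(gt, st, sm)
  expect_equal(mrca_copy_count(rec, "IJ"), 6)
})

test_that("within-species duplications below a node do not change its count", {
  st <- ape::read.tree(text = "(A:1,B:1)AB;")
  base <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  sm <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B",
          a1x = "A", a1y = "A")
  with_dup <- ape::read.tree(
    text = "(((a1x:0.3,a1y:0.3):0.7,b1:1):1,(a2:1,b2:1):1);")
  n0 <- mrca_copy_count(reconcile_lca(base, st, sm), "AB")
  n1 <- mrca_copy_count(reconcile_lca(with_dup, st, sm), "AB")
  expect_equal(n0, n1)
})

test_that("reconciling the true gene tree reproduces simulated history", {
  cfg <- sim_config(
    species_tree = "((A:0.4,B:0.4)AB:0.25,(C:0.45,D:0.45)CD:0.2)ABCD;",
    birth_rates = c(tandem = 0.4, segmental = 0.2, TE = 0, retro = 0))
  for (s in 1:15) {
    tr <- simulate_family_history(cfg, seed = 200 + s)
    if (nrow(tr$extant) < 4) next
    gt <- gene_tree_phylo(tr)
    rec <- reconcile_lca(gt$tree, tr$species_tree, gt$species_map)
    # loss-free: planted duplication count is recovered exactly
    expect_equal(sum(rec$events$event == "duplication"), nrow(tr$events))
    for (lbl in c("AB", "CD", "ABCD"))
      expect_equal(mrca_copy_count(rec, lbl), tr$mrca_counts[[lbl]],
                   label = paste("seed", 200 + s, lbl))
  }
})

test_that("reciprocal best pairs are mutual nearest cross-group genes", {
  ids <- c("m1", "m2", "m3", "d1", "d2", "d3")
  grp <- setNames(c("mono", "mono", "mono", "dico", "dico", "dico"), ids)
  d <- matrix(5, 6, 6, dimnames = list(ids, ids)); diag(d) <- 0
  d["m1", "d1"] <- d["d1", "m1"] <- 1
  d["m2", "d2"] <- d["d2", "m2"] <- 1.2
  d["m3", "d3"] <- d["d3", "m3"] <- 0.8
  rbp <- reciprocal_best_pairs(d, grp)
  expect_equal(nrow(rbp), 3)
  expect_setequal(paste(rbp$gene_a, rbp$gene_b),
                  c("d1 m1", "d2 m2", "d3 m3"))

  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"),
                                                  c("x", "y")))
  rbp2 <- reciprocal_best_pairs(two, c(x = "g1", y = "g2"))
  expect_equal(nrow(rbp2), 1)
  expect_equal(nrow(reciprocal_best_pairs(two, c(x = "g1", y = "g1"))), 0)

  tie <- matrix(c(0, 1, 1, 1, 0, 5, 1, 5, 0), 3,
                dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  expect_warning(reciprocal_best_pairs(tie, c(p = "g1", q = "g2",
                                              r = "g2")), "tie")
})
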