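test_that("an invariant codon column carries no selection signal", {
  tree <- ape::read.tree(text = "((t1:0.3,t2:0.3):0.24,(t3:0.3,t4:0.3):0.24);")
  aln <- structure(setNames(rep(paste(rep("ATG", 10), collapse = ""), 4),
                            tree$tip.label), class = "codon_alignment")
  sw <- sitewise_selection_scan(aln, tree)
  expect_true(all(sw$lrt_stat < 1e-6))
  expect_true(all(sw$class == "neutral"))
})

test_that("site likelihood equals direct summation over internal states", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.25);")
  # rooted 3-taxon tree: two internal nodes, 61^2 state combinations
  set.seed(30)
  for (r in 1:4) {
    cods <- sample(ORACLE_SENSE, 3)
    aln <- structure(setNames(cods, c("A", "B", "C")),
                     class = "codon_alignment")
    tip <- famevol:::codon_index_matrix(aln)
    kappa <- runif(1, 1, 4); omega <- runif(1, 0.1, 3)
    got <- famevol:::sitewise_loglik(tip, tree, kappa, omega, scale = 1)
    want <- oracle_site_loglik_3taxa(cods[1], cods[2], cods[3],
                                     0.2, 0.3, 0.15, 0.25, kappa, omega)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("all-gap sites are reported untested", {
  tree <- ape::read.tree(text = "((t1:0.3,t2:0.3):0.2,(t3:0.3,t4:0.3):0.2);")
  aln <- simulate_codon_alignment(tree, rep(0.5, 5), seed = 3)
  gapped <- vapply(as.character(aln), function(s)
    paste0(substr(s, 1, 6), "---", substr(s, 10, nchar(s))), character(1))
  caln <- structure(setNames(gapped, names(aln)), class = "codon_alignment")
  sw <- sitewise_selection_scan(caln, tree)
  expect_equal(sw$class[3], "untested")
  expect_false(sw$tested[3])
  expect_true(all(sw$tested[-3]))
})

test_that("the scan is deterministic and flags strong purifying sites", {
  tree <- ape::read.tree(text = "((t1:0.6,t2:0.6):0.5,(t3:0.6,t4:0.6):0.5);")
  aln <- simulate_codon_alignment(tree, rep(0.03, 60), seed = 7)
  sw1 <- sitewise_selection_scan(aln, tree)
  sw2 <- sitewise_selection_scan(aln, tree)
  expect_identical(sw1, sw2)
  expect_gt(mean(sw1$omega_hat < 1), 0.8)
  expect_gte(sum(sw1$class == "purifying"), 1)
})
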