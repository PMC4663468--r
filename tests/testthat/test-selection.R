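test_that("backtranslation places codons under residues and gaps as ---", {
  cds <- c(s1 = "ATGAAATTTTAA", s2 = "ATGCATTTT")
  aln <- c(s1 = "MKF", s2 = "MHF")
  caln <- backtranslate(aln, cds)
  expect_equal(unname(caln[["s1"]]), "ATGAAATTT")
  expect_equal(unname(caln[["s2"]]), "ATGCATTTT")

  aln_gap <- c(s1 = "MKF", s2 = "M-F")
  cds_gap <- c(s1 = "ATGAAATTT", s2 = "ATGTTT")
  caln2 <- backtranslate(aln_gap, cds_gap)
  expect_equal(unname(caln2[["s2"]]), "ATG---TTT")

  # mismatch names the offending residue
  bad <- c(s1 = "MKFMKFM", s2 = "MKFMKFM")
  cds_bad <- c(s1 = "ATGAAATTTATGAAATTTATG",
               s2 = "ATGAAATTTATGAAATTTTGG")  # residue 7 M vs W
  expect_error(backtranslate(bad, cds_bad), "residue 7")
})

test_that("pair filters apply the overlap and identity rules", {
  co <- function(n, codon = "ATG") paste(rep(codon, n), collapse = "")
  # 40 codons overlap = 120 bp -> too short
  short <- c(co(40), co(40))
  expect_equal(filter_pair_alignment(short)$reason, "length")
  # 100 codons, 35% of codons fully different -> identity < 70%
  set.seed(20)
  c1 <- random_codon_pair(100, max_diff = 0)$c1
  c2 <- c1
  c2[1:65] <- "GGG"; c1[1:65] <- "CCC"
  lowid <- c(paste(c1, collapse = ""), paste(c2, collapse = ""))
  expect_equal(filter_pair_alignment(lowid)$reason, "identity")
  good <- c(co(100, "ATG"), co(100, "ATG"))
  expect_true(filter_pair_alignment(good)$accept)
})

test_that("identical and synonymous-only pairs give the stated Ka/Ks", {
  set.seed(21)
  p <- random_codon_pair(80, max_diff = 0)
  same <- kaks_pair(c(paste(p$c1, collapse = ""),
                      paste(p$c1, collapse = "")))
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ratio))

  # introduce only synonymous third-position changes (fourfold codons)
  c1 <- rep("CTA", 80); c2 <- c1; c2[seq(1, 80, 8)] <- "CTG"
  syn <- kaks_pair(c(paste(c1, collapse = ""), paste(c2, collapse = "")))
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
  expect_equal(syn$ratio, 0)
})

test_that("NG86 counting matches the pathway oracle and is symmetric", {
  set.seed(22)
  for (r in 1:25) {
    p <- random_codon_pair(60)
    s1 <- paste(p$c1, collapse = ""); s2 <- paste(p$c2, collapse = "")
    got <- kaks_pair(c(s1, s2))
    want <- oracle_ng86(p$c1, p$c2)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$N, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$S + got$N, 3 * got$n_codons, tolerance = 1e-6)
    swapped <- kaks_pair(c(s2, s1))
    expect_equal(got$ka, swapped$ka, tolerance = 1e-12)
    expect_equal(got$ks, swapped$ks, tolerance = 1e-12)
  }
})

test_that("codon columns with gaps or N are dropped pairwise", {
  s1 <- "ATGAAA---CCC"
  s2 <- "ATGAANTTTCCC"
  r <- kaks_pair(c(s1, s2))
  expect_equal(r$n_codons, 2)  # ATG and CCC columns only
  expect_error(kaks_pair(c("TAAATG", "TAAATG")), "stop")
})

test_that("the YN00-compatible mode stays close to NG86 on evolved pairs", {
  tree <- ape::read.tree(text = "(x:0.15,y:0.15);")
  for (s in 1:6) {
    aln <- simulate_codon_alignment(tree, rep(0.4, 200), kappa = 3,
                                    seed = 1200 + s)
    ng <- kaks_pair(aln)
    yn <- kaks_pair(aln, method = "YN00")
    if (is.na(ng$ratio) || is.na(yn$ratio)) next
    expect_lt(abs(ng$ratio - yn$ratio), 0.2)
  }
})

test_that("Ka/Ks estimates order simulated selective regimes correctly", {
  tree <- ape::read.tree(text = "(x:0.2,y:0.2);")
  med <- function(w, seeds) {
    r <- vapply(seeds, function(s) {
      aln <- simulate_codon_alignment(tree, rep(w, 300), seed = s)
      kaks_pair(aln)$ratio
    }, numeric(1))
    median(r, na.rm = TRUE)
  }
  m_low <- med(0.1, 1:12)
  m_high <- med(2.0, 1:12)
  expect_lt(m_low, 0.5)
  expect_gt(m_high, m_low)
})
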