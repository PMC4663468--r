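test_that("profile columns score the shared residue highest", {
  aln <- c(s1 = "ACDEF", s2 = "ACDEF")
  prof <- build_domain_profile(aln)
  expect_equal(prof$consensus, "ACDEF")
  top <- apply(prof$pssm, 1, which.max)
  expect_equal(famevol:::AA_ALPHABET[top], strsplit("ACDEF", "")[[1]])
})

test_that("columns with half or more gaps are dropped", {
  aln <- c(a = "A-CDE", b = "A-CDE", c = "A-CDE", d = "AWCDE", e = "A-CDE")
  prof <- build_domain_profile(aln)   # column 2 is 80% gaps
  expect_equal(nrow(prof$pssm), 4)
  expect_equal(prof$consensus, "ACDE")
  expect_error(build_domain_profile(c(x = "--", y = "--")), "gap")
  expect_error(build_domain_profile(c(x = "AC")), "at least 2")
  expect_error(build_domain_profile(c(x = "AC", y = "ACD")), "unequal")
})

test_that("a seed sequence outscores its shuffles against the profile", {
  dom <- make_domain_seed(80, seed = 21)
  prof <- build_domain_profile(dom$alignment)
  enc <- famevol:::aa_encode(dom$alignment[[1]])
  self <- famevol:::.sw_profile_score(prof$pssm, enc, prof$gap_open,
                                      prof$gap_extend)
  set.seed(77)
  for (k in 1:20) {
    shuf <- famevol:::.sw_profile_score(prof$pssm, sample(enc),
                                        prof$gap_open, prof$gap_extend)
    expect_gte(self, shuf)
  }
})

test_that("a verbatim consensus is the top hit with full coverage", {
  dom <- make_domain_seed(80, seed = 8)
  prof <- build_domain_profile(dom$alignment, profile_id = "PF00862")
  set.seed(5)
  prots <- c(target = paste0(random_protein(30), dom$consensus,
                             random_protein(20)),
             other = random_protein(130))
  hits <- scan_proteins(prof, prots, seed = 2)
  expect_equal(hits$gene_id[1], "target")
  expect_equal(hits$profile_coverage[1], 1.0)
  expect_equal(hits$e_value[1], min(hits$e_value))
})

test_that("E-values are calibrated: about one random hit per scan", {
  dom <- make_domain_seed(80, seed = 31)
  prof <- build_domain_profile(dom$alignment)
  total <- 0; n_scans <- 6
  for (r in seq_len(n_scans)) {
    set.seed(400 + r)
    prots <- setNames(replicate(150, random_protein(200)),
                      paste0("r", 1:150))
    h <- scan_proteins(prof, prots, e_init = 1.0, n_prefilter = 200,
                       seed = r)
    total <- total + nrow(h)
  }
  # total ~ Poisson(n_scans); reject only gross miscalibration
  expect_lte(total, 4 * n_scans)
  expect_lte(abs(total - n_scans), 3 * sqrt(n_scans) + 2)
})

test_that("family assignment follows the domain-combination rules", {
  hit <- function(g, p, e) data.frame(
    gene_id = g, profile_id = p, bit_score = 50, e_value = e,
    prot_start = 1L, prot_end = 80L, profile_coverage = 0.95,
    stringsAsFactors = FALSE)
  hits <- rbind(hit("g_sps", "PF00534", 1e-6), hit("g_sps", "PF05116", 1e-5),
                hit("g_spp", "PF05116", 1e-4),
                hit("g_susy", "PF00862", 1e-8),
                hit("g_udp", "PF01704", 1e-7),
                hit("g_none", "PF00862", 0.5))
  asg <- assign_families(hits)
  fam <- setNames(asg$family, asg$gene_id)
  expect_equal(fam[["g_sps"]], "SPS")
  expect_equal(fam[["g_spp"]], "SPP")
  expect_equal(fam[["g_susy"]], "SuSy")
  expect_equal(fam[["g_udp"]], "UDPGP")
  expect_false("g_none" %in% asg$gene_id)
  # no gene is both SPS and SPP
  expect_false(any(duplicated(asg$gene_id)))

  # idempotent and order-independent
  asg2 <- assign_families(hits[sample(nrow(hits)), ])
  expect_equal(asg[order(asg$gene_id), ], asg2[order(asg2$gene_id), ],
               ignore_attr = TRUE)

  # cross-family conflict resolved by best E-value and recorded
  conf <- rbind(hit("g_mix", "PF00862", 1e-9), hit("g_mix", "PF01704", 1e-3))
  asg3 <- assign_families(conf)
  expect_equal(asg3$family, "SuSy")
  expect_length(attr(asg3, "conflicts"), 1)
})

test_that("partial members are excluded only without expression evidence", {
  asg <- data.frame(gene_id = c("a", "b", "c"),
                    family = "SuSy", best_e = 1e-9,
                    coverage = c(0.4, 0.4, 1.0), status = "full",
                    stringsAsFactors = FALSE)
  out <- flag_partial_members(asg, expression_evidence = "b",
                              min_coverage = 0.7)
  expect_equal(out$status, c("partial_excluded", "full", "full"))
})

test_that("family calls on a planted proteome reach 95% precision/recall", {
  sim <- simulate_proteome(n_per_family = 25, n_decoy = 1000, seed = 7)
  profiles <- lapply(names(sim$domains), function(pid)
    build_domain_profile(sim$domains[[pid]]$alignment, profile_id = pid))
  hits <- do.call(rbind, lapply(profiles, scan_proteins,
                                proteins = sim$proteins, seed = 5))
  asg <- assign_families(hits)
  merged <- merge(asg, sim$truth, by = "gene_id", all = TRUE)
  tp <- sum(!is.na(merged$family.x) & !is.na(merged$family.y) &
              merged$family.x == merged$family.y)
  fp <- sum(!is.na(merged$family.x) &
              (is.na(merged$family.y) | merged$family.x != merged$family.y))
  fn <- sum(is.na(merged$family.x) & !is.na(merged$family.y))
  expect_gte(tp / (tp + fp), 0.95)
  expect_gte(tp / (tp + fn), 0.95)
})
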