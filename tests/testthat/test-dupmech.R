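test_that("local alignment of identical proteins is exact self-match", {
  al <- local_align_proteins("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                             "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  expect_equal(al$identity, 100)
  expect_equal(al$query_coverage, 1.0)
  expect_error(local_align_proteins("MK1", "MK"), "non-amino-acid")
})

test_that("reversed random proteins align with low coverage", {
  low <- 0
  for (s in 1:8) {
    a <- random_protein(200, seed = 600 + s)
    b <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
    al <- local_align_proteins(a, b)
    if (al$query_coverage < 0.3) low <- low + 1
  }
  expect_gte(low, 7)
})

test_that("Smith-Waterman matches exhaustive enumeration on toy pairs", {
  sub <- famevol:::blosum62_matrix()
  alpha <- famevol:::AA_ALPHABET
  for (s in 1:6) {
    a <- random_protein(8, seed = 700 + s)
    b <- random_protein(8)
    al <- local_align_proteins(a, b)
    expect_equal(al$score,
                 oracle_local_align(a, b, sub, alpha), tolerance = 1e-9)
  }
})

test_that("qualifying tandem pairs merge into arrays by single linkage", {
  prot <- random_protein(150, seed = 11)
  ann <- fixture_family_row(3, gap_bp = 20000, protein = prot)
  arrays <- detect_tandem_arrays(c("g01", "g02", "g03"), ann)
  expect_length(arrays, 1)
  expect_equal(arrays[[1]]$member_ids, c("g01", "g02", "g03"))
  # input order does not matter; arrays partition their members
  arrays2 <- detect_tandem_arrays(c("g03", "g01", "g02"), ann)
  expect_equal(arrays[[1]]$member_ids, arrays2[[1]]$member_ids)
  expect_false(anyDuplicated(unlist(lapply(arrays, `[[`,
                                           "member_ids"))) > 0)
})

test_that("genome class selects the tandem distance window", {
  prot <- random_protein(150, seed = 12)
  # two genes 120 kb apart (span > 100 kb, < 350 kb)
  genes <- data.frame(gene_id = c("x1", "x2"), chromosome = "chr1",
                      strand = "+", start = c(1000, 121000),
                      end = c(2000, 122000), stringsAsFactors = FALSE)
  prots <- setNames(rep(prot, 2), genes$gene_id)
  std <- fixture_annotation(genes, proteins = prots,
                            genome_class = "standard")
  cmp <- fixture_annotation(genes, proteins = prots,
                            genome_class = "compact")
  expect_length(detect_tandem_arrays(genes$gene_id, std), 1)
  expect_length(detect_tandem_arrays(genes$gene_id, cmp), 0)
})

test_that("collinear chaining reports blocks of at least five anchors", {
  inst <- list(rank_a = 1:5, rank_b = 3:7, score = rep(10, 5))
  ca <- chain_instance_annotation(inst)
  blocks <- chain_collinear_blocks(ca$anchors, ca$annotation, ca$annotation)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_pairs, 5)

  inst4 <- list(rank_a = 1:4, rank_b = 3:6, score = rep(10, 4))
  ca4 <- chain_instance_annotation(inst4)
  expect_length(chain_collinear_blocks(ca4$anchors, ca4$annotation,
                                       ca4$annotation), 0)

  bad <- ca$anchors; bad$gene_a[1] <- "missing"
  expect_error(chain_collinear_blocks(bad, ca$annotation, ca$annotation),
               "unknown")
})

test_that("chain DP equals exhaustive search on random instances", {
  for (s in 1:25) {
    inst <- make_chain_instance(sample(3:8, 1), seed = 800 + s)
    ca <- chain_instance_annotation(inst)
    blocks <- chain_collinear_blocks(ca$anchors, ca$annotation,
                                     ca$annotation, min_pairs = 1)
    got <- max(vapply(blocks, `[[`, numeric(1), "chain_score"))
    want <- max(oracle_best_chain(inst$rank_a, inst$rank_b, inst$score),
                oracle_best_chain(inst$rank_a, -inst$rank_b, inst$score))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("segmental labels cover anchors and block spans only", {
  inst <- list(rank_a = 1:5, rank_b = 1:5, score = rep(10, 5))
  ca <- chain_instance_annotation(inst)
  blocks <- chain_collinear_blocks(ca$anchors, ca$annotation, ca$annotation)
  expect_true("A03" %in% classify_segmental("A03", blocks, ca$annotation))
  # gene far outside every block span on another part of the chromosome
  far <- classify_segmental("A25", blocks, ca$annotation, flank_bp = 10000)
  expect_length(far, 0)
  expect_length(classify_segmental("A01", list(), ca$annotation), 0)
})

test_that("TE-carried fragments are typed by the parent region they span", {
  parent_prot <- random_protein(200, seed = 13)
  mk_gene <- function(prot) list(gene_id = "g", chromosome = "chr1",
                                 start = 100, end = 200,
                                 protein_seq = prot)
  parent <- list(gene_id = "p", protein_seq = parent_prot)
  element <- list(chromosome = "chr1", start = 50, end = 400)
  whole <- classify_te_carried_fragment(mk_gene(parent_prot), element,
                                        parent)
  expect_equal(as.integer(whole), 1L)
  three_p <- classify_te_carried_fragment(
    mk_gene(substr(parent_prot, 121, 200)), element, parent)
  expect_equal(as.integer(three_p), 2L)
  five_p <- classify_te_carried_fragment(
    mk_gene(substr(parent_prot, 1, 80)), element, parent)
  expect_equal(as.integer(five_p), 3L)
  middle <- classify_te_carried_fragment(
    mk_gene(substr(parent_prot, 41, 140)), element, parent)
  expect_equal(as.integer(middle), 4L)
  off <- list(gene_id = "g", chromosome = "chr1", start = 500, end = 600,
              protein_seq = parent_prot)
  expect_error(classify_te_carried_fragment(off, element, parent),
               "overlap")
})

test_that("retrogene calls need a single exon and a multi-exon parent", {
  prot <- random_protein(150, seed = 14)
  genes <- data.frame(gene_id = c("single", "multi", "lone"),
                      chromosome = "chr1", strand = "+",
                      start = c(1000, 50000, 200000),
                      end = c(1450, 52000, 200450),
                      stringsAsFactors = FALSE)
  exons <- list(
    single = matrix(c(1000, 1450), 1,
                    dimnames = list(NULL, c("start", "end"))),
    multi = matrix(c(50000, 50100, 50500, 50600, 51000, 52000), 3, 2,
                   byrow = TRUE, dimnames = list(NULL, c("start", "end"))),
    lone = matrix(c(200000, 200450), 1,
                  dimnames = list(NULL, c("start", "end"))))
  prots <- c(single = prot, multi = prot,
             lone = random_protein(150, seed = 15))
  ann <- fixture_annotation(genes, proteins = prots, exons = exons)
  calls <- detect_retrogenes(c("single", "multi", "lone"), ann)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$retro_id, "single")
  expect_equal(calls$parent_id, "multi")
  expect_equal(calls$introns_lost, 2L)
  expect_false("multi" %in% calls$retro_id)
})

test_that("mechanism labels are multi-valued with no precedence", {
  asg <- data.frame(gene_id = c("t1", "dual", "plain"), family = "SuSy",
                    best_e = 1e-9, coverage = 1, status = "full",
                    stringsAsFactors = FALSE)
  arrays <- list(list(chromosome = "chr1", member_ids = c("t1", "dual"),
                      genome_class = "standard", pairs = NULL))
  te <- data.frame(gene_id = "dual", element_class = "LTR",
                   stringsAsFactors = FALSE)
  summ <- summarize_mechanisms(asg, arrays, segmental_ids = "dual",
                               te_calls = te)
  lab <- setNames(summ$gene_labels$mechanisms, summ$gene_labels$gene_id)
  expect_equal(lab[["t1"]], "tandem")
  expect_setequal(strsplit(lab[["dual"]], ",")[[1]],
                  c("tandem", "segmental", "TE"))
  expect_equal(lab[["plain"]], "none")
})
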