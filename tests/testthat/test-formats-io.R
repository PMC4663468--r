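test_that("CDS extraction splices exons and respects strand", {
  d <- withr::local_tempdir()
  fx <- write_tiny_gff_fasta(d)
  ann <- read_gff3_fasta(fx$gff, fx$fasta)
  expected <- paste0(substr(fx$chrom, 101, 160), substr(fx$chrom, 201, 260))
  expect_equal(ann$cds[["g1"]], expected)

  d2 <- withr::local_tempdir()
  fx2 <- write_tiny_gff_fasta(d2, minus_strand = TRUE)
  ann2 <- read_gff3_fasta(fx2$gff, fx2$fasta)
  expected2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(substr(fx2$chrom, 101, 160),
                                 substr(fx2$chrom, 201, 260)))))
  expect_equal(ann2$cds[["g1"]], expected2)
})

test_that("gene ranks order genes by start per chromosome", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chromosome = "chr1", strand = "+",
                      start = c(100, 5000, 900),
                      end = c(400, 5300, 1200), stringsAsFactors = FALSE)
  ann <- fixture_annotation(genes)
  expect_equal(ann$genes[c("gA", "gB", "gC"), "rank"], c(1L, 3L, 2L))
})

test_that("coordinates outside the chromosome are a named hard error", {
  genes <- data.frame(gene_id = "far", chromosome = "chr1", strand = "+",
                      start = 100, end = 2e7, stringsAsFactors = FALSE)
  expect_error(fixture_annotation(genes), "far")
})

test_that("a CDS not divisible by three is flagged partial and kept", {
  genes <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
                      start = 1, end = 10, stringsAsFactors = FALSE)
  ann <- fixture_annotation(genes, cds = c(g1 = "ATGAAACC"))
  expect_true(ann$genes["g1", "partial"])
  expect_true("g1" %in% rownames(ann$genes))
})

test_that("domtbl reading skips malformed rows and round-trips", {
  d <- withr::local_tempdir()
  path <- file.path(d, "hits.domtbl")
  good <- paste("geneA - 0 PF00862 - 100 1e-10 55.2 0.0 1 1 1e-10 1e-10",
                "55.2 0.0 1 90 10 120 10 120 0.9 -")
  good2 <- paste("geneB - 0 PF01704 - 80 0.003 21.0 0.0 1 1 0.003 0.003",
                 "21.0 0.0 1 60 5 70 5 70 0.9 -")
  bad <- paste("geneC - 0 PF01704 - 80 0.1 21.0 0.0 1 1 0.1 not_a_number",
               "21.0 0.0 1 60 5 70 5 70 0.9 -")
  writeLines(c("# comment", good, good2, bad), path)
  expect_warning(hits <- read_domtbl(path), "malformed")
  expect_equal(nrow(hits), 2)
  expect_equal(attr(hits, "n_skipped"), 1L)
  expect_equal(hits$gene_id, c("geneA", "geneB"))
  expect_equal(hits$e_value, c(1e-10, 0.003))

  out <- file.path(d, "rt.domtbl")
  write_domtbl(hits, out, profile_len = c(PF00862 = 100L, PF01704 = 80L))
  back <- read_domtbl(out)
  expect_equal(back$gene_id, hits$gene_id)
  expect_equal(back$e_value, hits$e_value, tolerance = 1e-6)
  expect_equal(back$prot_start, hits$prot_start)
  expect_equal(back$prot_end, hits$prot_end)
})

test_that("write_tables is deterministic with a stable header", {
  d <- withr::local_tempdir()
  df <- data.frame(id = c("b", "a", "c"), value = c(2, 1, 3))
  p1 <- file.path(d, "t1.tsv"); p2 <- file.path(d, "t2.tsv")
  write_tables(df, p1)
  write_tables(df[c(3, 1, 2), ], p2)
  expect_identical(readLines(p1), readLines(p2))
  empty <- df[0, ]
  p3 <- file.path(d, "t3.tsv")
  write_tables(empty, p3)
  expect_equal(readLines(p3), "id\tvalue")
})
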