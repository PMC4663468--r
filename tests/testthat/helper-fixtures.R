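# Small in-code fixtures shared across test files.

# annotation with genes placed by explicit coordinates; proteins/cds are
# optional named vectors
fixture_annotation <- function(genes, proteins = character(),
                               cds = character(), exons = NULL,
                               chrom_len = 1e7,
                               genome_class = "standard") {
  chroms <- unique(genes$chromosome)
  if (is.null(exons)) {
    exons <- lapply(seq_len(nrow(genes)), function(i)
      matrix(c(genes$start[i], genes$end[i]), 1,
             dimnames = list(NULL, c("start", "end"))))
    names(exons) <- genes$gene_id
  }
  genome_annotation(genes, exons, cds, proteins,
                    setNames(rep(chrom_len, length(chroms)), chroms),
                    genome_class = genome_class)
}

# evenly spaced same-protein family genes on one chromosome; gap_bp is the
# start-to-start spacing
fixture_family_row <- function(n, gap_bp = 20000, protein,
                               chrom = "chr1", gene_len = 1000,
                               prefix = "g") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  starts <- 1000 + (seq_len(n) - 1) * gap_bp
  genes <- data.frame(gene_id = ids, chromosome = chrom, strand = "+",
                      start = starts, end = starts + gene_len - 1,
                      stringsAsFactors = FALSE)
  fixture_annotation(genes, proteins = setNames(rep(protein, n), ids))
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

# random chaining instance: anchors with distinct ranks on two chromosomes
make_chain_instance <- function(n_anchor, seed) {
  set.seed(seed)
  ra <- sort(sample(1:20, n_anchor))
  rb <- sample(1:20, n_anchor)
  score <- round(runif(n_anchor, 1, 20), 2)
  list(rank_a = ra, rank_b = rb, score = score)
}

# annotation pair realizing a chain instance so chain_collinear_blocks can
# run on it: genes on chrA ordered by rank_a, genes on chrB by rank_b
chain_instance_annotation <- function(inst) {
  na <- length(inst$rank_a)
  ids_a <- sprintf("a%02d", seq_len(na))
  ids_b <- sprintf("b%02d", seq_len(na))
  max_rank <- 25
  mk <- function(chrom, pre) {
    ids <- sprintf("%s%02d", pre, 1:max_rank)
    starts <- 1000 + (0:(max_rank - 1)) * 5000
    data.frame(gene_id = ids, chromosome = chrom, strand = "+",
               start = starts, end = starts + 999, stringsAsFactors = FALSE)
  }
  genes <- rbind(mk("chrA", "A"), mk("chrB", "B"))
  ann <- fixture_annotation(genes)
  anchors <- data.frame(
    gene_a = sprintf("A%02d", inst$rank_a),
    gene_b = sprintf("B%02d", inst$rank_b),
    score = inst$score, stringsAsFactors = FALSE)
  list(annotation = ann, anchors = anchors)
}

# one-gene GFF3 + genome FASTA written to a temp dir
write_tiny_gff_fasta <- function(dir, minus_strand = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  # chromosome of 600 bp; gene with two exons 101-160 and 201-260
  set.seed(42)
  chrom <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  strand <- if (minus_strand) "-" else "+"
  gff <- c("##gff-version 3",
           paste("chr1", "test", "gene", 101, 260, ".", strand, ".",
                 "ID=g1", sep = "\t"),
           paste("chr1", "test", "mRNA", 101, 260, ".", strand, ".",
                 "ID=g1.t1;Parent=g1", sep = "\t"),
           paste("chr1", "test", "exon", 101, 160, ".", strand, ".",
                 "ID=g1.e1;Parent=g1.t1", sep = "\t"),
           paste("chr1", "test", "exon", 201, 260, ".", strand, ".",
                 "ID=g1.e2;Parent=g1.t1", sep = "\t"),
           paste("chr1", "test", "CDS", 101, 160, ".", strand, "0",
                 "ID=g1.c1;Parent=g1.t1", sep = "\t"),
           paste("chr1", "test", "CDS", 201, 260, ".", strand, "0",
                 "ID=g1.c2;Parent=g1.t1", sep = "\t"))
  gff_path <- file.path(dir, "test.gff3")
  writeLines(gff, gff_path)
  fa_path <- file.path(dir, "genome.fasta")
  writeLines(c(">chr1", chrom), fa_path)
  list(gff = gff_path, fasta = fa_path, chrom = chrom)
}
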