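# Readers/writers for external formats and the in-memory annotation
# container. Coordinates are 1-based inclusive throughout (GFF3 convention).

#' Construct a genome annotation object
#'
#' The central container for gene models: a per-gene table of coordinates
#' plus parallel lists of exon tables and CDS/protein sequences. Per
#' chromosome, genes carry a 1-based ordinal `rank` (sorted by start) used by
#' the tandem-array and collinearity detectors.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `strand`
#'   (`+`/`-`), `start`, `end` (1-based inclusive bp).
#' @param exons named list (by gene id) of two-column matrices of exon
#'   `start`,`end` coordinates, sorted and non-overlapping.
#' @param cds named character vector of stranded 5'->3' CDS sequences.
#' @param protein named character vector of protein sequences.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param genome_class `"standard"` or `"compact"`; selects the tandem
#'   distance window (350 kb vs 100 kb, the latter for small genomes such as
#'   algae and *Arabidopsis*).
#' @param chrom_seq optional named character vector of chromosome
#'   sequences (required by the TE structural detectors).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, cds, protein, chrom_lengths,
                              genome_class = c("standard", "compact"),
                              chrom_seq = NULL) {
  genome_class <- match.arg(genome_class)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chromosome", "strand", "start", "end") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in annotation")
  bad <- genes$start > genes$end
  if (any(bad))
    stop("start > end for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  over <- genes$end > chrom_lengths[genes$chromosome]
  if (any(is.na(over) | over))
    stop("feature outside chromosome bounds: ",
         paste(genes$gene_id[which(is.na(over) | over)], collapse = ", "))
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  genes$rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    i <- which(genes$chromosome == chr)
    genes$rank[i] <- seq_along(i)
  }
  genes$n_exons <- vapply(genes$gene_id, function(g) {
    ex <- exons[[g]]
    if (is.null(ex)) 1L else nrow(ex)
  }, integer(1))
  if (is.null(genes$partial)) {
    genes$partial <- vapply(genes$gene_id, function(g) {
      if (!g %in% names(cds)) return(FALSE)
      s <- cds[[g]]
      !is.na(s) && nchar(s) %% 3 != 0
    }, logical(1))
  }
  rownames(genes) <- genes$gene_id
  structure(list(genes = genes, exons = exons, cds = cds, protein = protein,
                 chrom_lengths = chrom_lengths, genome_class = genome_class,
                 chrom_seq = chrom_seq),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_lengths), "chromosome(s);",
      "class", x$genome_class, "\n")
  invisible(x)
}

#' Retrieve one gene model from an annotation
#'
#' @param annotation a [genome_annotation()] object.
#' @param gene_id gene identifier.
#' @return A list with the gene's coordinates, exon table, rank, CDS and
#'   protein sequence.
#' @export
gene_model <- function(annotation, gene_id) {
  g <- annotation$genes[gene_id, ]
  if (is.na(g$gene_id)) stop("unknown gene id: ", gene_id)
  list(gene_id = g$gene_id, chromosome = g$chromosome, strand = g$strand,
       start = g$start, end = g$end, rank = g$rank,
       exons = annotation$exons[[gene_id]],
       cds_seq = unname(annotation$cds[gene_id]),
       protein_seq = unname(annotation$protein[gene_id]),
       partial = g$partial)
}

gff_attr <- function(attr, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  m <- regexpr(pat, attr, perl = TRUE)
  res <- rep(NA_character_, length(attr))
  ok <- m > 0
  res[ok] <- sub(pat, "\\1", regmatches(attr, m), perl = TRUE)
  res
}

#' Read gene models from GFF3 plus FASTA sequences
#'
#' Builds a [genome_annotation()] from a GFF3 file and a genome FASTA. When
#' no CDS FASTA is given, CDS sequences are spliced out of the genome
#' (reverse-complemented on the minus strand). One locus is represented by
#' its longest-CDS transcript; alternative isoforms are collapsed. Genes
#' whose CDS length is not a multiple of three are flagged `partial` and
#' retained (they are excluded from codon-level analyses downstream).
#'
#' @param gff3_path path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome_fasta path to the genome FASTA.
#' @param cds_fasta,protein_fasta optional FASTA paths keyed by gene id;
#'   when absent, sequences are derived from the genome.
#' @param genome_class passed to [genome_annotation()].
#' @return A `genome_annotation`.
#' @export
read_gff3_fasta <- function(gff3_path, genome_fasta, cds_fasta = NULL,
                            protein_fasta = NULL,
                            genome_class = c("standard", "compact")) {
  genome_class <- match.arg(genome_class)
  gff <- ape::read.gff(gff3_path, GFF3 = TRUE)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))

  gff$ID <- gff_attr(gff$attributes, "ID")
  gff$Parent <- gff_attr(gff$attributes, "Parent")

  genes <- gff[gff$type == "gene", ]
  if (nrow(genes) == 0) stop("no gene features in ", gff3_path)
  mrna <- gff[gff$type == "mRNA", ]
  cdsf <- gff[gff$type == "CDS", ]
  exof <- gff[gff$type == "exon", ]

  # map transcripts to genes; tolerate CDS/exon attached directly to genes
  tx2gene <- setNames(mrna$Parent, mrna$ID)
  seg_gene <- function(seg) {
    p <- seg$Parent
    g <- tx2gene[p]
    ifelse(is.na(g), p, g)
  }
  cdsf$gene <- seg_gene(cdsf)
  cdsf$tx <- ifelse(cdsf$Parent %in% names(tx2gene), cdsf$Parent, cdsf$gene)
  exof$gene <- seg_gene(exof)
  exof$tx <- ifelse(exof$Parent %in% names(tx2gene), exof$Parent, exof$gene)

  bad <- genes$end > chrom_lengths[as.character(genes$seqid)] |
    is.na(chrom_lengths[as.character(genes$seqid)])
  if (any(bad))
    stop("feature outside chromosome: ",
         paste(genes$ID[bad], collapse = ", "))

  exons <- list(); cds <- character(); protein <- character()
  cds_given <- if (!is.null(cds_fasta)) {
    x <- Biostrings::readDNAStringSet(cds_fasta)
    names(x) <- sub("\\s.*$", "", names(x)); x
  } else NULL
  prot_given <- if (!is.null(protein_fasta)) {
    x <- Biostrings::readAAStringSet(protein_fasta)
    names(x) <- sub("\\s.*$", "", names(x)); x
  } else NULL

  for (k in seq_len(nrow(genes))) {
    gid <- genes$ID[k]
    chr <- as.character(genes$seqid[k])
    strand <- as.character(genes$strand[k])
    segs <- cdsf[cdsf$gene == gid, ]
    # longest-CDS transcript per locus
    if (nrow(segs) > 0 && length(unique(segs$tx)) > 1) {
      lens <- tapply(segs$end - segs$start + 1, segs$tx, sum)
      segs <- segs[segs$tx == names(which.max(lens)), ]
    }
    exseg <- exof[exof$tx %in% unique(segs$tx) | exof$gene == gid, ]
    if (nrow(exseg) > 0 && length(unique(exseg$tx)) > 1)
      exseg <- exseg[exseg$tx == unique(segs$tx)[1], ]
    use <- if (nrow(exseg) > 0) exseg else segs
    if (nrow(use) > 0) {
      m <- as.matrix(use[order(use$start), c("start", "end")])
      dimnames(m) <- list(NULL, c("start", "end"))
      exons[[gid]] <- m
    } else {
      exons[[gid]] <- matrix(c(genes$start[k], genes$end[k]), 1,
                             dimnames = list(NULL, c("start", "end")))
    }
    if (!is.null(cds_given) && gid %in% names(cds_given)) {
      cds[gid] <- as.character(cds_given[[gid]])
    } else if (nrow(segs) > 0) {
      segs <- segs[order(segs$start), ]
      if (any(segs$end > chrom_lengths[chr]))
        stop("CDS outside chromosome for gene ", gid)
      pieces <- substring(as.character(genome[[chr]]), segs$start, segs$end)
      s <- paste(pieces, collapse = "")
      if (strand == "-") s <- reverse_complement(s)
      cds[gid] <- s
    }
    if (!is.null(prot_given) && gid %in% names(prot_given)) {
      protein[gid] <- as.character(prot_given[[gid]])
    } else if (gid %in% names(cds) && !is.na(cds[[gid]]) &&
               nchar(cds[[gid]]) %% 3 == 0) {
      protein[gid] <- translate_cds(cds[[gid]])
    }
  }

  gdf <- data.frame(gene_id = genes$ID,
                    chromosome = as.character(genes$seqid),
                    strand = as.character(genes$strand),
                    start = genes$start, end = genes$end,
                    stringsAsFactors = FALSE)
  genome_annotation(gdf, exons, cds, protein, chrom_lengths, genome_class,
                    chrom_seq = setNames(as.character(genome),
                                         names(genome)))
}

#' Translate a CDS, dropping a terminal stop if encoded
#' @noRd
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Read a domtblout-style domain hit table
#'
#' Whitespace-delimited dialect of the per-domain scanner output (comment
#' lines start with `#`). Malformed rows are skipped with a warning; the
#' skip count is attached as attribute `n_skipped`.
#'
#' @param path file path.
#' @return data.frame of domain hits (`gene_id`, `profile_id`, `bit_score`,
#'   `e_value`, `prot_start`, `prot_end`, `profile_coverage`).
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- list(); skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 21) { skipped <- skipped + 1L; next }
    num <- suppressWarnings(as.numeric(f[c(3, 6, 13, 14, 16, 17, 20, 21)]))
    if (anyNA(num)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = f[1], profile_id = f[4], bit_score = num[4],
      e_value = num[3], prot_start = as.integer(num[7]),
      prot_end = as.integer(num[8]),
      profile_coverage = (num[6] - num[5] + 1) / num[2],
      stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(skipped, " malformed domtbl row(s) skipped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), profile_id = character(),
               bit_score = numeric(), e_value = numeric(),
               prot_start = integer(), prot_end = integer(),
               profile_coverage = numeric())
  attr(out, "n_skipped") <- skipped
  out
}

#' Write domain hits in the domtblout dialect
#'
#' Inverse of [read_domtbl()] for the columns famevol uses; remaining
#' columns are written as placeholders.
#'
#' @param hits data.frame as returned by [read_domtbl()] or
#'   [scan_proteins()]; requires a profile length attribute or
#'   `profile_len` column to reconstruct coordinates.
#' @param path output path.
#' @param profile_len named integer vector of profile lengths.
#' @export
write_domtbl <- function(hits, path, profile_len) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# famevol domain hit table (domtblout dialect)", con)
  for (i in seq_len(nrow(hits))) {
    plen <- profile_len[[hits$profile_id[i]]]
    hmm_to <- as.integer(round(hits$profile_coverage[i] * plen))
    writeLines(paste(
      hits$gene_id[i], "-", "0", hits$profile_id[i], "-", plen,
      format(hits$e_value[i], digits = 8), hits$bit_score[i], "0.0", "1", "1",
      format(hits$e_value[i], digits = 8),
      format(hits$e_value[i], digits = 8),
      hits$bit_score[i], "0.0", "1", hmm_to,
      hits$prot_start[i], hits$prot_end[i],
      hits$prot_start[i], hits$prot_end[i], "0.9", "-",
      sep = " "), con)
  }
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, UTF-8, `.` decimal separator; rows sorted by the first
#' column (then the second, if present) so repeated runs are byte-identical.
#'
#' @param x data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tables <- function(x, path) {
  stopifnot(is.data.frame(x))
  if (nrow(x) > 0) {
    ord <- if (ncol(x) >= 2) order(x[[1]], x[[2]]) else order(x[[1]])
    x <- x[ord, , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write named sequences as wrapped FASTA
#' @param seqs named character vector (DNA or protein).
#' @param path output path.
#' @param type `"dna"` or `"aa"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
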