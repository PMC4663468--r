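# Genome-layout side of the simulator: materializing TE structural
# signatures, building annotated genomes with known mechanism labels, and
# emitting standard-format datasets with a truth log.

#' Build one transposable element with its class signature
#'
#' Constructs the element sequence around an optional cargo sequence:
#' LTR (two identical TG...CA long terminal repeats), Helitron (5'
#' family-consensus terminus beginning TC, GC-rich terminal hairpin, CTAG
#' 3' terminus), CACTA (TIRs beginning CACTA), MULE (long TIRs) or hAT
#' (short TIRs). The flanking TSD (where the class has one) is applied at
#' insertion time by [insert_te()].
#'
#' @param element_class TE class name.
#' @param cargo sequence carried inside the element (may be empty).
#' @param seed integer seed.
#' @return list with `seq`, `tsd_len`, `element_class` and class-specific
#'   feature coordinates relative to the element.
#' @export
build_te_element <- function(element_class, cargo = "", seed = 1) {
  set.seed(seed)
  pad <- function(n) random_dna(n)
  if (element_class == "LTR") {
    ltr <- paste0("TG", pad(296), "CA")
    internal <- paste0(pad(500), cargo, pad(700))
    if (nchar(internal) < 1100) internal <- paste0(internal,
                                                  pad(1100 - nchar(internal)))
    seq <- paste0(ltr, internal, ltr)
    return(list(element_class = "LTR", seq = seq, tsd_len = 5L,
                ltr_len = nchar(ltr),
                cargo_offset = nchar(ltr) + 500L))
  }
  if (element_class == "Helitron") {
    arm <- paste(sample(c("G", "C"), 7, replace = TRUE), collapse = "")
    pal <- paste0(arm, "A", reverse_complement(arm))
    seq <- paste0("TCTCTACTA", pad(400), cargo, pad(120), pal, pad(4),
                  "CTAG")
    return(list(element_class = "Helitron", seq = seq, tsd_len = 0L,
                cargo_offset = 9L + 400L))
  }
  if (element_class == "CACTA") {
    tir <- paste0("CACTA", pad(15))
    seq <- paste0(tir, pad(300), cargo, pad(300), reverse_complement(tir))
    return(list(element_class = "CACTA", seq = seq, tsd_len = 3L,
                tir_len = nchar(tir), cargo_offset = nchar(tir) + 300L))
  }
  if (element_class == "MULE") {
    tir <- pad(45)
    seq <- paste0(tir, pad(250), cargo, pad(250), reverse_complement(tir))
    return(list(element_class = "MULE", seq = seq, tsd_len = 9L,
                tir_len = 45L, cargo_offset = 45L + 250L))
  }
  if (element_class == "hAT") {
    tir <- pad(12)
    seq <- paste0(tir, pad(200), cargo, pad(200), reverse_complement(tir))
    return(list(element_class = "hAT", seq = seq, tsd_len = 8L,
                tir_len = 12L, cargo_offset = 12L + 200L))
  }
  stop("unknown element class: ", element_class)
}

#' Insert a TE element into a host sequence with its target-site duplication
#'
#' The `tsd_len` bases at the insertion point are duplicated around the
#' element. For Helitrons (no TSD) the invariant host nucleotides are
#' enforced: the base before the element is set to A and the base after
#' to T.
#'
#' @param host host sequence.
#' @param pos insertion point (element starts at this position in the
#'   returned sequence, after accounting for the left TSD copy).
#' @param element a [build_te_element()] result.
#' @return list with `seq`, and the element's `start`/`end` (1-based) in it.
#' @export
insert_te <- function(host, pos, element) {
  n <- nchar(host)
  stopifnot(pos > element$tsd_len + 1, pos < n - element$tsd_len)
  if (element$element_class == "Helitron") {
    left <- paste0(substr(host, 1, pos - 2), "A")
    right <- paste0("T", substr(host, pos + 1, n))
    seq <- paste0(left, element$seq, right)
    return(list(seq = seq, start = pos, end = pos + nchar(element$seq) - 1,
                tsd = ""))
  }
  tsd <- substr(host, pos, pos + element$tsd_len - 1)
  seq <- paste0(substr(host, 1, pos + element$tsd_len - 1),
                element$seq, tsd,
                substr(host, pos + element$tsd_len, n))
  list(seq = seq, start = pos + element$tsd_len,
       end = pos + element$tsd_len + nchar(element$seq) - 1, tsd = tsd)
}

#' Simulate a 50-kb window with one planted TE element
#'
#' Convenience wrapper used for detector calibration: a random host window
#' at the configured GC content with a single mutation-free element (and
#' optional cargo) inserted near the middle.
#'
#' @param element_class TE class.
#' @param window_bp window size.
#' @param cargo optional cargo sequence.
#' @param gc host GC content.
#' @param mutation_rate per-base substitution probability applied to the
#'   element after insertion (0 = mutation-free).
#' @param seed integer seed.
#' @return list with `seq`, true `start`/`end` of the element, and `tsd`.
#' @export
simulate_te_window <- function(element_class, window_bp = 50000, cargo = "",
                               gc = 0.4, mutation_rate = 0, seed = 1) {
  set.seed(seed)
  host <- random_dna(window_bp, gc)
  el <- build_te_element(element_class, cargo, seed = child_seed(seed, 7))
  set.seed(child_seed(seed, 13))
  pos <- sample(seq(10000, window_bp - nchar(el$seq) - 10000), 1)
  ins <- insert_te(host, pos, el)
  if (mutation_rate > 0) {
    chars <- strsplit(ins$seq, "")[[1]]
    idx <- ins$start:ins$end
    mut <- idx[runif(length(idx)) < mutation_rate]
    chars[mut] <- vapply(chars[mut], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    ins$seq <- paste(chars, collapse = "")
  }
  ins$element_class <- element_class
  ins
}

#' Simulate a proteome with planted domain families
#'
#' Plants `n_per_family` proteins for each family: the family's domain
#' consensus (with per-residue substitutions at `mut_prob`) embedded in
#' random flanks, plus `n_decoy` random background proteins. SPS proteins
#' carry both of their defining domains.
#'
#' @param domains named list of [make_domain_seed()] results keyed by
#'   profile id (defaults cover the four family-defining profiles).
#' @param n_per_family planted genes per family.
#' @param n_decoy random decoy proteins.
#' @param mut_prob substitution rate applied to each planted domain copy.
#' @param seed integer seed.
#' @return list with `proteins` (named vector), `truth` (data.frame
#'   `gene_id`, `family`) and `domains`.
#' @export
simulate_proteome <- function(domains = NULL, n_per_family = 25,
                              n_decoy = 1000, mut_prob = 0.08, seed = 1) {
  if (is.null(domains)) {
    ids <- c("PF00862", "PF00534", "PF05116", "PF01704")
    domains <- setNames(lapply(seq_along(ids), function(k)
      make_domain_seed(100, seed = child_seed(seed, 100 + k))), ids)
  }
  set.seed(child_seed(seed, 3))
  mutate_domain <- function(cons) {
    s <- strsplit(cons, "")[[1]]
    mut <- runif(length(s)) < mut_prob
    s[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }
  rand_prot <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE,
                                        prob = ROBINSON_FREQS),
                                 collapse = "")
  proteins <- character(); truth <- list()
  k <- 0L
  for (fam in names(FAMILY_DOMAINS)) {
    for (i in seq_len(n_per_family)) {
      k <- k + 1L
      id <- sprintf("%s_p%03d", fam, i)
      doms <- vapply(FAMILY_DOMAINS[[fam]], function(pid)
        mutate_domain(domains[[pid]]$consensus), character(1))
      prot <- paste0(rand_prot(sample(30:80, 1)),
                     paste(vapply(doms, function(d)
                       paste0(d, rand_prot(sample(10:40, 1))),
                       character(1)), collapse = ""),
                     rand_prot(sample(20:60, 1)))
      proteins[id] <- prot
      truth[[id]] <- data.frame(gene_id = id, family = fam,
                                stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_decoy)) {
    id <- sprintf("decoy_%04d", i)
    proteins[id] <- rand_prot(sample(150:400, 1))
  }
  list(proteins = proteins, truth = do.call(rbind, truth),
       domains = domains)
}

# --- single-species annotated genome with known mechanism labels ---------

codons_to_exons <- function(cds, n_exons, intron_lens) {
  n <- nchar(cds)
  if (n_exons == 1) return(list(pieces = cds, introns = character()))
  cuts <- sort(sample(seq(10, n - 10), n_exons - 1))
  starts <- c(1, cuts + 1); ends <- c(cuts, n)
  list(pieces = substring(cds, starts, ends),
       introns = vapply(intron_lens, random_dna, character(1)))
}

#' Simulate an annotated genome with a planted mechanism mix
#'
#' Builds one species' genome directly: a family of genes carrying the
#' diagnostic domain, expanded by known mechanisms. Tandem copies are
#' placed next to their source with 0-2 intervening filler genes;
#' segmental copies are placed on a second chromosome inside a duplicated
#' run of at least five flanking genes (the collinear anchors); TE copies
#' are wrapped in a structural element of a random class; retro copies are
#' single-exon copies of a multi-exon source. Copies differ from their
#' source by `copy_mut` nucleotide substitutions per site.
#'
#' @param n_tandem_pairs,n_segmental,n_te,n_retro,n_ancestral counts of
#'   genes created by each route (`n_segmental` counts source+copy pairs;
#'   both members of a tandem or segmental pair are labeled with the
#'   mechanism, matching what positional evidence can recover).
#' @param config a [sim_config()].
#' @param copy_mut per-site substitution rate applied to each new copy.
#' @param seed integer seed.
#' @return list with `annotation` ([genome_annotation()]), `genome` (named
#'   chromosome sequences), `truth` (gene_id, mechanism, te_class),
#'   `te_truth` (planted element coordinates) and `domain`.
#' @export
simulate_mechanism_genome <- function(n_tandem_pairs = 5, n_segmental = 3,
                                      n_te = 3, n_retro = 2,
                                      n_ancestral = 4, config = sim_config(),
                                      copy_mut = 0.03, seed = 1) {
  set.seed(seed)
  domain <- make_domain_seed(config$domain_range[2] -
                               config$domain_range[1] + 1,
                             seed = child_seed(seed, 991))
  L <- config$gene_codons
  base_codons <- random_sense_codons(L)
  base_codons[config$domain_range[1]:config$domain_range[2]] <-
    aa_to_codon(domain$consensus)
  base_cds <- paste(base_codons, collapse = "")
  mutate_cds <- function(cds, rate) {
    codons <- split_codons(cds)
    sc <- sense_codons()
    idx <- match(codons, sc)
    nmut <- rbinom(1, nchar(cds), rate)
    for (i in sample(seq_along(codons), min(nmut, length(codons)))) {
      nb <- which(codon_space()$syn_ts[idx[i], ] +
                    codon_space()$syn_tv[idx[i], ] +
                    codon_space()$ns_ts[idx[i], ] +
                    codon_space()$ns_tv[idx[i], ] > 0)
      idx[i] <- sample(nb, 1)
    }
    paste(sc[idx], collapse = "")
  }
  gid <- local({ k <- 0L; function(pre) { k <<- k + 1L
    sprintf("%s_%03d", pre, k) } })
  fam <- list()   # per family gene: id, cds, mech, te_class, n_exons, place
  add_gene <- function(mech, cds, te_class = NA, n_exons = config$n_exons,
                       anchor = NA) {
    id <- gid("FAM")
    fam[[id]] <<- list(id = id, cds = cds, mech = mech,
                       te_class = te_class, n_exons = n_exons,
                       anchor = anchor)
    id
  }
  for (i in seq_len(n_ancestral))
    add_gene("none", mutate_cds(base_cds, 0.08))
  for (i in seq_len(n_tandem_pairs)) {
    src <- add_gene("tandem", mutate_cds(base_cds, 0.08))
    add_gene("tandem", mutate_cds(fam[[src]]$cds, copy_mut), anchor = src)
  }
  seg_sources <- character()
  for (i in seq_len(n_segmental)) {
    src <- add_gene("segmental", mutate_cds(base_cds, 0.08))
    cp <- add_gene("segmental", mutate_cds(fam[[src]]$cds, copy_mut),
                   anchor = src)
    seg_sources <- c(seg_sources, src)
  }
  te_classes <- names(config$te_class_probs)
  for (i in seq_len(n_te)) {
    src <- add_gene("none", mutate_cds(base_cds, 0.08))
    add_gene("TE", mutate_cds(fam[[src]]$cds, copy_mut),
             te_class = te_classes[1 + (i - 1) %% length(te_classes)],
             anchor = src)
  }
  for (i in seq_len(n_retro)) {
    src <- add_gene("none", mutate_cds(base_cds, 0.08))
    add_gene("retro", mutate_cds(fam[[src]]$cds, copy_mut), n_exons = 1,
             anchor = src)
  }

  filler_cds <- function() paste(random_sense_codons(sample(120:220, 1)),
                                 collapse = "")
  # chromosome assembly
  genes_df <- list(); exons <- list(); cds_v <- character()
  te_truth <- list()
  build_chrom <- function(chrom, items) {
    # items: list of list(id, cds, n_exons, te=NULL) in placement order
    seqparts <- character(); pos <- 0L
    add_seq <- function(s) { seqparts[[length(seqparts) + 1L]] <<- s
      pos <<- pos + nchar(s) }
    for (it in items) {
      add_seq(random_dna(sample(1500:4000, 1), config$gc))
      ex <- codons_to_exons(it$cds, it$n_exons,
                            sample(120:300, max(it$n_exons - 1, 0),
                                   replace = TRUE))
      body <- ex$pieces[1]
      if (length(ex$pieces) > 1)
        for (k in 2:length(ex$pieces))
          body <- paste0(body, ex$introns[k - 1], ex$pieces[k])
      if (!is.null(it$te)) {
        el <- build_te_element(it$te, cargo = body,
                               seed = child_seed(seed, 500 + pos))
        host <- random_dna(2000, config$gc)
        ins <- insert_te(host, 1000, el)
        te_start <- pos + ins$start
        gene_start <- pos + ins$start - 1 + el$cargo_offset + 1
        add_seq(ins$seq)
        te_truth[[it$id]] <<- data.frame(
          gene_id = it$id, element_class = it$te,
          start = te_start, end = pos - (nchar(ins$seq) - ins$end),
          chromosome = chrom, stringsAsFactors = FALSE)
      } else {
        gene_start <- pos + 1L
        add_seq(body)
      }
      # exon coordinates within body
      off <- gene_start - 1L
      exl <- list(); p <- 0L
      for (k in seq_along(ex$pieces)) {
        exl[[k]] <- c(off + p + 1L, off + p + nchar(ex$pieces[k]))
        p <- p + nchar(ex$pieces[k]) +
          if (k < length(ex$pieces)) nchar(ex$introns[k]) else 0L
      }
      em <- do.call(rbind, exl)
      colnames(em) <- c("start", "end")
      genes_df[[it$id]] <<- data.frame(
        gene_id = it$id, chromosome = chrom, strand = "+",
        start = em[1, 1], end = em[nrow(em), 2], stringsAsFactors = FALSE)
      exons[[it$id]] <<- em
      cds_v[it$id] <<- it$cds
    }
    add_seq(random_dna(3000, config$gc))
    paste(seqparts, collapse = "")
  }

  ids <- names(fam)
  mech_of <- vapply(fam, `[[`, character(1), "mech")
  anchor_of <- vapply(fam, function(g)
    if (is.na(g$anchor %||% NA)) NA_character_ else g$anchor, character(1))
  # chr1: everything except segmental copies; tandem copies adjacent to src
  chr1_items <- list()
  filler_item <- function() {
    id <- gid("FIL")
    list(id = id, cds = filler_cds(), n_exons = sample(2:3, 1))
  }
  seg_copy_ids <- ids[mech_of == "segmental" & !is.na(anchor_of)]
  chr1_order <- setdiff(ids, seg_copy_ids)
  # place tandem copies immediately after their source
  placed <- character()
  flank_map <- list()  # segmental source -> its neighbor filler items
  for (id in chr1_order) {
    if (id %in% placed) next
    g <- fam[[id]]
    if (!is.na(anchor_of[id]) && mech_of[id] == "tandem") next # placed w/ src
    is_seg_src <- id %in% seg_sources
    # at least 11 intervening genes between distinct family placements so
    # unrelated (but still similar) family members never satisfy the
    # tandem proximity criterion
    pre_fillers <- replicate(11, filler_item(), simplify = FALSE)
    for (f in pre_fillers) chr1_items[[length(chr1_items) + 1L]] <- f
    item <- list(id = id, cds = g$cds, n_exons = g$n_exons)
    if (g$mech == "TE" && !is.na(g$te_class)) item$te <- g$te_class
    chr1_items[[length(chr1_items) + 1L]] <- item
    placed <- c(placed, id)
    if (is_seg_src) {
      post_fillers <- replicate(2, filler_item(), simplify = FALSE)
      for (f in post_fillers) chr1_items[[length(chr1_items) + 1L]] <- f
      # duplicate the three fillers nearest the gene plus the two after it
      flank_map[[id]] <- list(pre = pre_fillers[9:11], post = post_fillers)
    }
    # tandem children right after, with one intervening filler
    kids <- ids[anchor_of == id & mech_of == "tandem" & !is.na(anchor_of)]
    for (kid in kids) {
      chr1_items[[length(chr1_items) + 1L]] <- filler_item()
      chr1_items[[length(chr1_items) + 1L]] <-
        list(id = kid, cds = fam[[kid]]$cds, n_exons = fam[[kid]]$n_exons)
      placed <- c(placed, kid)
    }
  }
  for (i in seq_len(5)) chr1_items[[length(chr1_items) + 1L]] <- filler_item()
  # chr2: each segmental copy sits inside a duplicated run of its source's
  # chr1 neighborhood (3 upstream + 2 downstream duplicated fillers), so
  # the block has >= 5 contiguous collinear anchor pairs
  chr2_items <- list()
  for (id in seg_copy_ids) {
    src <- anchor_of[id]
    nb <- flank_map[[src]]
    dupit <- function(f) list(id = gid("FILDUP"),
                              cds = mutate_cds(f$cds, copy_mut),
                              n_exons = f$n_exons, src = f$id)
    run <- c(lapply(nb$pre, dupit),
             list(list(id = id, cds = fam[[id]]$cds,
                       n_exons = fam[[id]]$n_exons)),
             lapply(nb$post, dupit))
    for (it in run) chr2_items[[length(chr2_items) + 1L]] <- it
    chr2_items[[length(chr2_items) + 1L]] <- filler_item()
  }
  if (length(chr2_items) == 0)
    for (i in 1:3) chr2_items[[length(chr2_items) + 1L]] <- filler_item()

  dup_pairs <- list()
  for (it in c(chr1_items, chr2_items))
    if (!is.null(it$src))
      dup_pairs[[length(dup_pairs) + 1L]] <- data.frame(
        gene_a = it$src, gene_b = it$id, stringsAsFactors = FALSE)

  chr1_seq <- build_chrom("chr1", chr1_items)
  chr2_seq <- build_chrom("chr2", chr2_items)
  genome <- c(chr1 = chr1_seq, chr2 = chr2_seq)
  gdf <- do.call(rbind, genes_df)
  prot <- vapply(cds_v, translate_cds, character(1))
  ann <- genome_annotation(gdf, exons, cds_v, prot,
                           setNames(nchar(genome), names(genome)),
                           genome_class = "standard", chrom_seq = genome)
  truth <- data.frame(gene_id = ids, mechanism = mech_of,
                      te_class = vapply(fam, function(g)
                        as.character(g$te_class %||% NA), character(1)),
                      anchor = anchor_of, stringsAsFactors = FALSE)
  te_truth <- if (length(te_truth)) do.call(rbind, te_truth) else
    data.frame(gene_id = character(), element_class = character(),
               start = integer(), end = integer(), chromosome = character())
  rownames(truth) <- NULL; rownames(te_truth) <- NULL
  list(annotation = ann, genome = genome, truth = truth,
       te_truth = te_truth, domain = domain,
       filler_dup_pairs = if (length(dup_pairs)) do.call(rbind, dup_pairs)
       else NULL)
}

#' Write a genome annotation as GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- annotation$genes[order(annotation$genes$chromosome,
                              annotation$genes$start), ]
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    base <- paste(g$chromosome[i], "famevol", sep = "\t")
    writeLines(paste(g$chromosome[i], "famevol", "gene", g$start[i],
                     g$end[i], ".", g$strand[i], ".",
                     paste0("ID=", id), sep = "\t"), con)
    writeLines(paste(g$chromosome[i], "famevol", "mRNA", g$start[i],
                     g$end[i], ".", g$strand[i], ".",
                     paste0("ID=", id, ".t1;Parent=", id), sep = "\t"), con)
    ex <- annotation$exons[[id]]
    for (k in seq_len(nrow(ex))) {
      writeLines(paste(g$chromosome[i], "famevol", "exon", ex[k, 1],
                       ex[k, 2], ".", g$strand[i], ".",
                       paste0("ID=", id, ".e", k, ";Parent=", id, ".t1"),
                       sep = "\t"), con)
      writeLines(paste(g$chromosome[i], "famevol", "CDS", ex[k, 1],
                       ex[k, 2], ".", g$strand[i], "0",
                       paste0("ID=", id, ".c", k, ";Parent=", id, ".t1"),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs the family history, evolves sequences, lays out one annotated
#' genome per species (TE copies wrapped in structural elements), and
#' simulates an expression matrix for the focal (first) species. With
#' `out_dir` set, writes `genome.fasta`, `annotation.gff3`, `cds.fasta`,
#' `proteins.fasta`, `expression.tsv`, `species_tree.nwk`, `truth.json`
#' and `manifest.json` (see [emit_dataset()]).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisible bundle list (`truth`, `seqs`, `genomes`, `expression`,
#'   and per-species annotations).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1,
                             out_dir = NULL, force = FALSE) {
  truth <- simulate_family_history(config, seed)
  seqs <- evolve_codon_sequences(truth, config, child_seed(seed, 2))
  truth$extant$domain_frac <- unname(seqs$domain_frac[truth$extant$gene_id])
  gt <- gene_tree_phylo(truth)
  genomes <- list()
  for (sp in sort(unique(truth$extant$species))) {
    genomes[[sp]] <- layout_history_species(truth, seqs, sp, config,
                                            child_seed(seed, 20 + match(
                                              sp, sort(unique(
                                                truth$extant$species)))))
  }
  tab <- table(truth$extant$species)
  focal <- names(tab)[order(-tab, names(tab))][1]
  focal_genes <- truth$extant$gene_id[truth$extant$species == focal]
  pairs <- sibling_pairs(gt$tree, focal_genes)
  expr <- simulate_expression(
    c(focal_genes,
      grep("^FIL", rownames(genomes[[focal]]$annotation$genes),
           value = TRUE)),
    pairs, config, child_seed(seed, 5))
  bundle <- list(truth = truth, seqs = seqs, genomes = genomes,
                 gene_tree = gt, expression = expr, config = config,
                 seed = seed)
  if (!is.null(out_dir)) emit_dataset(bundle, out_dir, force = force)
  invisible(bundle)
}

# most-recent within-species paralog pairs (mutually nearest by patristic
# distance)
sibling_pairs <- function(tree, gene_ids) {
  gene_ids <- intersect(gene_ids, tree$tip.label)
  if (length(gene_ids) < 2)
    return(data.frame(gene_a = character(), gene_b = character()))
  d <- ape::cophenetic.phylo(tree)[gene_ids, gene_ids, drop = FALSE]
  diag(d) <- Inf
  rows <- list()
  for (a in gene_ids) {
    b <- gene_ids[which.min(d[a, ])]
    if (gene_ids[which.min(d[b, ])] == a && a < b)
      rows[[length(rows) + 1L]] <- data.frame(gene_a = a, gene_b = b,
                                              stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character())
}

# Lay out one species' extant genes on a chromosome pair according to
# their recorded origin mechanisms (history-driven version of
# simulate_mechanism_genome's layout).
layout_history_species <- function(truth, seqs, species, config, seed) {
  set.seed(seed)
  ext <- truth$extant[truth$extant$species == species, , drop = FALSE]
  fam <- list()
  for (i in seq_len(nrow(ext))) {
    id <- ext$gene_id[i]
    fam[[id]] <- list(id = id, cds = seqs$cds[[id]],
                      mech = ext$origin[i], te_class = ext$te_class[i],
                      n_exons = if (!is.na(ext$origin[i]) &&
                                    ext$origin[i] == "retro") 1L else
                        config$n_exons)
  }
  build_species_layout(fam, config, species, seed)
}

# shared layout engine: fam = named list of gene items (id, cds, mech,
# te_class, n_exons)
build_species_layout <- function(fam, config, species, seed) {
  gid <- local({ k <- 0L; function(pre) { k <<- k + 1L
    sprintf("%s_%s%03d", species, pre, k) } })
  filler_item <- function()
    list(id = gid("FIL"), cds = paste(random_sense_codons(
      sample(120:220, 1)), collapse = ""), n_exons = sample(2:3, 1))
  items <- list()
  ids <- names(fam)
  mechs <- vapply(fam, `[[`, character(1), "mech")
  ord <- order(match(mechs, c("ancestral", "segmental", "TE", "retro",
                              "tandem")))
  prev_tandem <- FALSE
  for (id in ids[ord]) {
    g <- fam[[id]]
    # tandem-derived genes cluster together (one intervening filler);
    # every other placement gets 11 intervening fillers so similarity
    # alone cannot satisfy the tandem proximity criterion
    n_sep <- if (identical(g$mech, "tandem") && prev_tandem) 1 else 11
    prev_tandem <- identical(g$mech, "tandem")
    for (i in seq_len(n_sep)) items[[length(items) + 1L]] <- filler_item()
    item <- list(id = id, cds = g$cds, n_exons = g$n_exons)
    if (identical(g$mech, "TE") && !is.na(g$te_class))
      item$te <- g$te_class
    items[[length(items) + 1L]] <- item
  }
  for (i in 1:3) items[[length(items) + 1L]] <- filler_item()

  genes_df <- list(); exons <- list(); cds_v <- character()
  te_truth <- list()
  seqparts <- character(); pos <- 0L
  add_seq <- function(s) { seqparts[[length(seqparts) + 1L]] <<- s
    pos <<- pos + nchar(s) }
  chrom <- paste0(species, "_chr1")
  for (it in items) {
    add_seq(random_dna(sample(1500:4000, 1), config$gc))
    if (is.null(it$cds) || is.na(it$cds) || nchar(it$cds) < 30) next
    ex <- codons_to_exons(it$cds, it$n_exons,
                          sample(120:300, max(it$n_exons - 1, 0),
                                 replace = TRUE))
    body <- ex$pieces[1]
    if (length(ex$pieces) > 1)
      for (k in 2:length(ex$pieces))
        body <- paste0(body, ex$introns[k - 1], ex$pieces[k])
    if (!is.null(it$te)) {
      el <- build_te_element(it$te, cargo = body,
                             seed = child_seed(seed, 700 + pos %% 1000))
      host <- random_dna(2000, config$gc)
      ins <- insert_te(host, 1000, el)
      gene_start <- pos + ins$start - 1 + el$cargo_offset + 1
      te_truth[[it$id]] <- data.frame(
        gene_id = it$id, element_class = it$te, start = pos + ins$start,
        end = pos + ins$end, chromosome = chrom, stringsAsFactors = FALSE)
      add_seq(ins$seq)
    } else {
      gene_start <- pos + 1L
      add_seq(body)
    }
    off <- gene_start - 1L
    exl <- list(); p <- 0L
    for (k in seq_along(ex$pieces)) {
      exl[[k]] <- c(off + p + 1L, off + p + nchar(ex$pieces[k]))
      p <- p + nchar(ex$pieces[k]) +
        if (k < length(ex$pieces)) nchar(ex$introns[k]) else 0L
    }
    em <- do.call(rbind, exl); colnames(em) <- c("start", "end")
    genes_df[[it$id]] <- data.frame(
      gene_id = it$id, chromosome = chrom, strand = "+",
      start = em[1, 1], end = em[nrow(em), 2], stringsAsFactors = FALSE)
    exons[[it$id]] <- em
    cds_v[it$id] <- it$cds
  }
  add_seq(random_dna(3000, config$gc))
  genome <- setNames(paste(seqparts, collapse = ""), chrom)
  gdf <- do.call(rbind, genes_df)
  prot <- vapply(cds_v, translate_cds, character(1))
  ann <- genome_annotation(gdf, exons, cds_v, prot,
                           setNames(nchar(genome), names(genome)),
                           chrom_seq = genome)
  te_truth <- if (length(te_truth)) do.call(rbind, te_truth) else
    data.frame(gene_id = character(), element_class = character(),
               start = integer(), end = integer(), chromosome = character())
  rownames(te_truth) <- NULL
  list(annotation = ann, genome = genome, te_truth = te_truth)
}

#' Write a simulated dataset bundle to standard-format files
#'
#' @param bundle result of [simulate_dataset()].
#' @param out_dir output directory (created if missing; must be empty or
#'   `force = TRUE`).
#' @param force overwrite existing files.
#' @return the directory path, invisibly.
#' @export
emit_dataset <- function(bundle, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- unlist(lapply(bundle$genomes, `[[`, "genome"))
  names(genome) <- sub("^[^.]*\\.", "", names(genome))
  write_fasta(genome, file.path(out_dir, "genome.fasta"), "dna")
  cds <- character(); prot <- character()
  gdf <- list(); exall <- list()
  for (sp in names(bundle$genomes)) {
    ann <- bundle$genomes[[sp]]$annotation
    cds <- c(cds, ann$cds); prot <- c(prot, ann$protein)
    gdf[[sp]] <- ann$genes
    exall <- c(exall, ann$exons)
  }
  allg <- do.call(rbind, gdf); rownames(allg) <- allg$gene_id
  lens <- unlist(lapply(bundle$genomes, function(g)
    setNames(nchar(g$genome), names(g$genome))))
  names(lens) <- sub("^[^.]*\\.", "", names(lens))
  allann <- genome_annotation(allg, exall, cds, prot, lens)
  write_gff3(allann, file.path(out_dir, "annotation.gff3"))
  write_fasta(cds, file.path(out_dir, "cds.fasta"), "dna")
  write_fasta(prot, file.path(out_dir, "proteins.fasta"), "aa")
  em <- bundle$expression$matrix
  df <- data.frame(gene_id = rownames(em), em, check.names = FALSE)
  write_tables(df, file.path(out_dir, "expression.tsv"))
  groups <- data.frame(sample = names(bundle$expression$groups),
                       tissue = unname(bundle$expression$groups))
  write_tables(groups, file.path(out_dir, "sample_groups.tsv"))
  ape::write.tree(bundle$truth$species_tree,
                  file.path(out_dir, "species_tree.nwk"))
  write_fasta(bundle$seqs$domain$alignment,
              file.path(out_dir, "seed_PF00862.fasta"), "aa")
  truth_json <- list(
    extant = bundle$truth$extant,
    events = bundle$truth$events,
    mrca_counts = as.list(bundle$truth$mrca_counts),
    te_elements = do.call(rbind, lapply(bundle$genomes, `[[`, "te_truth")),
    expression_divergence = bundle$expression$truth,
    fragments = bundle$seqs$fragments)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_json <- jsonlite::toJSON(bundle$config[!vapply(bundle$config,
                                                    is.function,
                                                    logical(1))],
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(seed = bundle$seed,
                   config_hash = sum(utf8ToInt(cfg_json)) %% 1000000007,
                   n_genes = nrow(bundle$truth$extant))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
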