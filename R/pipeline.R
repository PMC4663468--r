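# Pipeline orchestration: census -> duplication mechanisms -> phylogeny and
# ancestral copy counts -> pairwise selection -> expression divergence,
# with a report mirroring the census / mechanism / MRCA / Ka-Ks summary
# tables.

#' Load an emitted dataset directory
#'
#' Reads the files written by [emit_dataset()] back through the standard
#' readers ([read_gff3_fasta()] etc.), splitting genes into per-species
#' annotations by the species prefix of their chromosome names.
#'
#' @param dir dataset directory.
#' @return list with `annotations` (per species), `species_tree`,
#'   `expression` (`matrix` + `groups`), and `seed_alignments`.
#' @export
load_dataset <- function(dir) {
  ann <- read_gff3_fasta(file.path(dir, "annotation.gff3"),
                         file.path(dir, "genome.fasta"),
                         cds_fasta = file.path(dir, "cds.fasta"),
                         protein_fasta = file.path(dir, "proteins.fasta"))
  species <- unique(sub("_chr.*$", "", ann$genes$chromosome))
  annotations <- list()
  for (sp in species) {
    sel <- ann$genes$chromosome %in%
      grep(paste0("^", sp, "_"), names(ann$chrom_lengths), value = TRUE)
    ids <- ann$genes$gene_id[sel]
    chroms <- grep(paste0("^", sp, "_"), names(ann$chrom_lengths),
                   value = TRUE)
    annotations[[sp]] <- genome_annotation(
      ann$genes[sel, c("gene_id", "chromosome", "strand", "start", "end")],
      ann$exons[ids], ann$cds[ids], ann$protein[ids],
      ann$chrom_lengths[chroms],
      chrom_seq = ann$chrom_seq[chroms])
  }
  st <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  expr <- NULL
  if (file.exists(file.path(dir, "expression.tsv"))) {
    em <- read.table(file.path(dir, "expression.tsv"), header = TRUE,
                     sep = "\t", check.names = FALSE)
    rownames(em) <- em$gene_id
    gm <- read.table(file.path(dir, "sample_groups.tsv"), header = TRUE,
                     sep = "\t")
    expr <- list(matrix = as.matrix(em[, -1, drop = FALSE]),
                 groups = setNames(gm$tissue, gm$sample))
  }
  seeds <- list()
  for (f in dir(dir, pattern = "^seed_.*\\.fasta$")) {
    pid <- sub("^seed_(.*)\\.fasta$", "\\1", f)
    x <- Biostrings::readAAStringSet(file.path(dir, f))
    seeds[[pid]] <- setNames(as.character(x), names(x))
  }
  list(annotations = annotations, species_tree = st, expression = expr,
       seed_alignments = seeds)
}

#' Run the full family analysis pipeline
#'
#' Stages: (1) census of every genome by profile scan plus the
#' domain-combination rules; (2) expansion-mechanism classification
#' (tandem, segmental via 50-kb window collinearity, TE structural
#' detection in 50-kb flanks, retrogenes); (3) family gene tree (NJ on
#' Poisson distances), minimum-duplication rooting, reconciliation and
#' ancestral copy counts; (4) reciprocal-best-pair Ka/Ks with the group
#' comparison; (5) paralog expression divergence when an expression matrix
#' is supplied. Stages degrade gracefully: with no species tree the
#' reconciliation stage is skipped, with no expression matrix the
#' divergence section is absent.
#'
#' @param annotations named list of [genome_annotation()] per genome.
#' @param seed_alignments named list (by profile id, e.g. `PF00862`) of
#'   seed alignments for [build_domain_profile()].
#' @param species_tree optional rooted `phylo`.
#' @param genome_groups optional named vector genome -> group (e.g.
#'   monocot/dicot) for the Ka/Ks comparison; defaults to one group per
#'   genome.
#' @param expression optional list with `matrix`, `groups` and optionally
#'   `pairs`.
#' @param run_sitewise run the sitewise scan on the family alignment
#'   (slower; off by default).
#' @param e_init,e_confirm census cutoffs.
#' @param flank_bp window half-width for segmental and TE detection.
#' @param seed integer seed for the scan nulls.
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(annotations, seed_alignments, species_tree = NULL,
                         genome_groups = NULL, expression = NULL,
                         run_sitewise = FALSE, e_init = 1.0,
                         e_confirm = 0.01, flank_bp = 50000, seed = 1) {
  if (length(annotations) == 0) stop("no annotations supplied")
  if (is.null(names(annotations))) stop("annotations must be named")
  if (length(seed_alignments) == 0)
    stop("no seed alignments supplied (census stage input missing)")
  profiles <- lapply(names(seed_alignments), function(pid)
    build_domain_profile(seed_alignments[[pid]], profile_id = pid))
  names(profiles) <- names(seed_alignments)

  census <- list(); mech <- list(); te_all <- list()
  for (gn in names(annotations)) {
    ann <- annotations[[gn]]
    prots <- ann$protein[!is.na(ann$protein)]
    hits <- do.call(rbind, lapply(profiles, scan_proteins, proteins = prots,
                                  e_init = e_init, seed = seed))
    asg <- assign_families(hits, e_confirm = e_confirm)
    asg <- flag_partial_members(asg)
    asg$genome <- if (nrow(asg)) gn else character(0)
    census[[gn]] <- asg
    mech[[gn]] <- classify_genome_mechanisms(asg, ann, flank_bp = flank_bp)
  }
  census_tab <- do.call(rbind, census)
  census_counts <- as.data.frame(table(genome = census_tab$genome,
                                       family = census_tab$family))
  names(census_counts)[3] <- "n_genes"

  # phylogeny + MRCA per family (needs >= 3 usable members and a species
  # tree)
  mrca_tab <- NULL; trees <- list()
  if (!is.null(species_tree)) {
    mrca_rows <- list()
    for (fam in unique(census_tab$family)) {
      members <- census_tab$gene_id[census_tab$family == fam &
                                      census_tab$status == "full"]
      prots <- unlist(lapply(annotations, function(a)
        a$protein[intersect(members, names(a$protein))]))
      names(prots) <- sub("^[^.]*\\.", "", names(prots))
      lens <- nchar(prots)
      prots <- prots[lens == as.integer(names(sort(-table(lens)))[1])]
      if (length(prots) < 3) next
      spmap <- setNames(sub("_.*$", "", names(prots)), names(prots))
      if (!all(spmap %in% species_tree$tip.label)) next
      d <- protein_distance_matrix(prots)
      gt <- nj_tree(d)
      rooted <- root_min_dup(gt, species_tree, spmap)
      rec <- reconcile_lca(rooted, species_tree, spmap)
      trees[[fam]] <- rec
      ntip_s <- length(species_tree$tip.label)
      for (k in seq_len(species_tree$Nnode)) {
        lbl <- if (!is.null(species_tree$node.label))
          species_tree$node.label[k] else paste0("node", k)
        cnt <- mrca_copy_count(rec, ntip_s + k)
        mrca_rows[[length(mrca_rows) + 1L]] <- data.frame(
          family = fam, species_node = lbl, copies = cnt,
          stringsAsFactors = FALSE)
      }
    }
    if (length(mrca_rows)) mrca_tab <- do.call(rbind, mrca_rows)
  }

  # pairwise Ka/Ks on reciprocal best cross-group pairs
  kaks_tab <- NULL
  groups <- genome_groups
  if (is.null(groups)) groups <- setNames(names(annotations),
                                          names(annotations))
  kaks_rows <- list()
  all_cds <- unlist(unname(lapply(annotations, `[[`, "cds")))
  for (fam in unique(census_tab$family)) {
    sub <- census_tab[census_tab$family == fam &
                        census_tab$status == "full", ]
    if (nrow(sub) < 2) next
    prots <- unlist(lapply(names(annotations), function(gn) {
      p <- annotations[[gn]]$protein[intersect(
        sub$gene_id[sub$genome == gn],
        names(annotations[[gn]]$protein))]
      p
    }))
    lens <- nchar(prots)
    prots <- prots[lens == as.integer(names(sort(-table(lens)))[1])]
    if (length(prots) < 2) next
    gene_groups <- setNames(
      groups[census_tab$genome[match(names(prots), census_tab$gene_id)]],
      names(prots))
    if (length(unique(gene_groups)) < 2) next
    d <- protein_distance_matrix(prots)
    rbp <- reciprocal_best_pairs(d, gene_groups)
    for (k in seq_len(nrow(rbp))) {
      a <- rbp$gene_a[k]; b <- rbp$gene_b[k]
      caln <- backtranslate(
        setNames(prots[c(a, b)], c(a, b)), all_cds)
      fl <- filter_pair_alignment(caln)
      if (!fl$accept) next
      kk <- tryCatch(kaks_pair(caln), error = function(e) NULL)
      if (is.null(kk)) next
      kaks_rows[[length(kaks_rows) + 1L]] <- data.frame(
        family = fam, gene_a = a, gene_b = b, ka = kk$ka, ks = kk$ks,
        ratio = kk$ratio, group_a = gene_groups[[a]],
        group_b = gene_groups[[b]], stringsAsFactors = FALSE)
    }
  }
  if (length(kaks_rows)) kaks_tab <- do.call(rbind, kaks_rows)

  sitewise_tab <- NULL
  if (run_sitewise && length(trees) > 0) {
    sw_rows <- list()
    for (fam in names(trees)) {
      rec <- trees[[fam]]
      prots <- character()
      for (a in annotations) prots <- c(prots, a$protein)
      sel <- rec$gene_tree$tip.label
      aln <- setNames(prots[sel], sel)
      caln <- backtranslate(aln, all_cds)
      sw <- sitewise_selection_scan(caln, rec$gene_tree)
      sw$family <- fam
      sw_rows[[fam]] <- sw
    }
    sitewise_tab <- do.call(rbind, sw_rows)
  }

  div_tab <- NULL
  if (!is.null(expression)) {
    norm <- normalize_expression(expression$matrix)
    pairs <- expression$pairs
    if (is.null(pairs)) {
      # closest same-genome paralog pairs from the census
      pr <- list()
      for (gn in names(annotations)) {
        ids <- intersect(census_tab$gene_id[census_tab$genome == gn],
                         rownames(norm))
        if (length(ids) < 2) next
        prots <- annotations[[gn]]$protein[ids]
        lens <- nchar(prots)
        prots <- prots[lens == as.integer(names(sort(-table(lens)))[1])]
        if (length(prots) < 2) next
        d <- protein_distance_matrix(prots)
        diag(d) <- Inf
        for (a in rownames(d)) {
          b <- colnames(d)[which.min(d[a, ])]
          if (colnames(d)[which.min(d[b, ])] == a && a < b)
            pr[[length(pr) + 1L]] <- data.frame(gene_a = a, gene_b = b,
                                                stringsAsFactors = FALSE)
        }
      }
      pairs <- if (length(pr)) do.call(rbind, pr) else NULL
    }
    if (!is.null(pairs) && nrow(pairs) > 0) {
      rows <- list()
      for (k in seq_len(nrow(pairs))) {
        a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
        if (!all(c(a, b) %in% rownames(norm))) next
        dv <- paralog_divergence_test(a, b, norm, expression$groups)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = a, gene_b = b, is_divergent = dv$is_divergent,
          n_divergent_tissues = length(dv$divergent_tissues),
          divergent_tissues = paste(dv$divergent_tissues, collapse = ","),
          stringsAsFactors = FALSE)
      }
      if (length(rows)) div_tab <- do.call(rbind, rows)
    }
  }

  mech_tab <- do.call(rbind, lapply(names(mech), function(gn) {
    m <- mech[[gn]]$summary
    if (is.null(m) || nrow(m) == 0) return(NULL)
    m$genome <- gn
    m
  }))
  gene_mech <- do.call(rbind, lapply(names(mech), function(gn) {
    m <- mech[[gn]]$gene_labels
    if (is.null(m) || nrow(m) == 0) return(NULL)
    m$genome <- gn
    m
  }))

  structure(list(census = census_tab, census_counts = census_counts,
                 mechanisms = mech_tab, gene_mechanisms = gene_mech,
                 mrca = mrca_tab, kaks = kaks_tab,
                 kaks_summary = if (!is.null(kaks_tab))
                   summarize_kaks_distribution(kaks_tab) else NULL,
                 sitewise = sitewise_tab, divergence = div_tab,
                 reconciliations = trees),
            class = "pipeline_report")
}

# Mechanism classification for one genome's census
classify_genome_mechanisms <- function(assignments, annotation,
                                       flank_bp = 50000) {
  if (nrow(assignments) == 0)
    return(list(gene_labels = NULL, summary = NULL, tandem = list(),
                segmental = character(), te = NULL, retro = NULL))
  res_t <- list(); seg_ids <- character(); te_rows <- list()
  for (fam in unique(assignments$family)) {
    fg <- assignments$gene_id[assignments$family == fam]
    res_t[[fam]] <- detect_tandem_arrays(fg, annotation)
    seg_ids <- c(seg_ids, segmental_for_family(fg, annotation, flank_bp))
    te_rows[[fam]] <- te_for_family(fg, annotation, flank_bp)
  }
  tandem_all <- do.call(c, unname(res_t))
  te_calls <- do.call(rbind, te_rows)
  retro <- do.call(rbind, lapply(unique(assignments$family), function(fam)
    detect_retrogenes(assignments$gene_id[assignments$family == fam],
                      annotation)))
  summ <- summarize_mechanisms(assignments, tandem_all %||% list(),
                               unique(seg_ids), te_calls, retro)
  c(summ, list(tandem = tandem_all, segmental = unique(seg_ids),
               te = te_calls, retro = retro))
}

# anchors between 50-kb windows around family-gene pairs, then chaining
segmental_for_family <- function(family_genes, annotation, flank_bp) {
  g <- annotation$genes
  out <- character()
  fg <- intersect(family_genes, rownames(g))
  if (length(fg) < 2) return(out)
  win_genes <- function(id) {
    gi <- g[id, ]
    rownames(g)[g$chromosome == gi$chromosome &
                  g$end >= gi$start - flank_bp &
                  g$start <= gi$end + flank_bp]
  }
  for (i in seq_len(length(fg) - 1)) for (j in (i + 1):length(fg)) {
    a <- fg[i]; b <- fg[j]
    wa <- win_genes(a); wb <- win_genes(b)
    if (g[a, "chromosome"] == g[b, "chromosome"] &&
        abs(g[a, "rank"] - g[b, "rank"]) <= 12) next  # same neighborhood
    anchors <- list()
    for (x in wa) for (y in wb) {
      px <- annotation$protein[[x]]; py <- annotation$protein[[y]]
      if (is.null(px) || is.null(py) || is.na(px) || is.na(py)) next
      al <- local_align_proteins(px, py)
      if (al$e_value <= 0.01)
        anchors[[length(anchors) + 1L]] <- data.frame(
          gene_a = x, gene_b = y, score = al$score,
          stringsAsFactors = FALSE)
    }
    if (length(anchors) == 0) next
    blocks <- chain_collinear_blocks(do.call(rbind, anchors), annotation,
                                     annotation)
    hit <- classify_segmental(c(a, b), blocks, annotation,
                              flank_bp = flank_bp)
    out <- c(out, hit)
  }
  unique(out)
}

te_for_family <- function(family_genes, annotation, flank_bp) {
  g <- annotation$genes
  rows <- list()
  for (id in intersect(family_genes, rownames(g))) {
    gi <- g[id, ]
    if (is.null(annotation$chrom_seq)) break
    chrom_len <- annotation$chrom_lengths[[gi$chromosome]]
    lo <- max(1, gi$start - flank_bp)
    hi <- min(chrom_len, gi$end + flank_bp)
    win <- substr(annotation$chrom_seq[[gi$chromosome]], lo, hi)
    for (cls in c("LTR", "Helitron", "CACTA", "MULE", "hAT")) {
      det <- detect_te_elements(win, cls)
      if (nrow(det) == 0) next
      det$start <- det$start + lo - 1L
      det$end <- det$end + lo - 1L
      inside <- det$start <= gi$start & det$end >= gi$end
      if (any(inside))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = id, element_class = cls,
          start = det$start[which(inside)[1]],
          end = det$end[which(inside)[1]], stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), element_class = character(),
               start = integer(), end = integer())
}

#' Summarize a Ka/Ks result table by group
#'
#' Histogram over `[0, 2]` with bin width 0.1 plus an overflow bin, group
#' means of Ka, Ks and their ratio, and a two-sample t-test comparing the
#' two groups' ratios (flagged significant at p < 0.05). Undefined ratios
#' (Ks = 0) are counted separately and excluded from means and tests.
#'
#' @param kaks data.frame with `ka`, `ks`, `ratio` and `group_a` (used as
#'   the group label of the pair).
#' @param bin_width histogram bin width.
#' @return list with `histogram`, `means`, `comparison`.
#' @export
summarize_kaks_distribution <- function(kaks, bin_width = 0.1) {
  kaks$group <- kaks$group_a %||% "all"
  if (is.null(kaks$group)) kaks$group <- "all"
  groups <- sort(unique(kaks$group))
  breaks <- c(seq(0, 2, by = bin_width), Inf)
  hist_rows <- list(); mean_rows <- list()
  for (g in groups) {
    sub <- kaks[kaks$group == g, ]
    def <- sub[!is.na(sub$ratio), ]
    if (nrow(sub) == 0) { warning("empty group ", g, " omitted"); next }
    cuts <- cut(def$ratio, breaks, right = FALSE,
                include.lowest = TRUE)
    tab <- table(cuts)
    hist_rows[[g]] <- data.frame(group = g, bin = names(tab),
                                 count = as.integer(tab),
                                 stringsAsFactors = FALSE)
    mean_rows[[g]] <- data.frame(
      group = g, n_pairs = nrow(sub), n_undefined = sum(is.na(sub$ratio)),
      mean_ka = mean(sub$ka), mean_ks = mean(sub$ks),
      mean_ratio = if (nrow(def)) mean(def$ratio) else NA_real_,
      stringsAsFactors = FALSE)
  }
  comparison <- NULL
  if (length(groups) == 2) {
    r1 <- kaks$ratio[kaks$group == groups[1] & !is.na(kaks$ratio)]
    r2 <- kaks$ratio[kaks$group == groups[2] & !is.na(kaks$ratio)]
    if (length(r1) >= 2 && length(r2) >= 2 &&
        (sd(r1) > 0 || sd(r2) > 0)) {
      tt <- t.test(r1, r2)
      comparison <- data.frame(group_1 = groups[1], group_2 = groups[2],
                               mean_1 = mean(r1), mean_2 = mean(r2),
                               p_value = tt$p.value,
                               significant = tt$p.value < 0.05)
    }
  }
  list(histogram = do.call(rbind, hist_rows),
       means = do.call(rbind, mean_rows), comparison = comparison)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  census:", nrow(x$census), "family genes across",
      length(unique(x$census$genome)), "genome(s)\n")
  if (!is.null(x$mrca))
    cat("  MRCA table:", nrow(x$mrca), "rows\n")
  if (!is.null(x$kaks))
    cat("  Ka/Ks pairs:", nrow(x$kaks), "\n")
  if (!is.null(x$divergence))
    cat("  divergence-tested pairs:", nrow(x$divergence), "\n")
  invisible(x)
}

#' Write a pipeline report to TSV files plus a markdown summary
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("census", "census_counts", "mechanisms", "gene_mechanisms",
            "mrca", "kaks", "sitewise", "divergence")
  for (tb in tabs) {
    t <- report[[tb]]
    if (!is.null(t) && nrow(t) > 0)
      write_tables(t, file.path(dir, paste0(tb, ".tsv")))
  }
  md <- c("# Gene family analysis report", "",
          paste0("- family genes: ", nrow(report$census)),
          paste0("- genomes: ",
                 paste(sort(unique(report$census$genome)), collapse = ", ")))
  if (!is.null(report$kaks_summary$means)) {
    md <- c(md, "", "## Mean Ka/Ks by group", "")
    m <- report$kaks_summary$means
    md <- c(md, paste0("- ", m$group, ": Ka ", round(m$mean_ka, 3),
                       ", Ks ", round(m$mean_ks, 3), ", Ka/Ks ",
                       round(m$mean_ratio, 3)))
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
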