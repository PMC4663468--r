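# Expansion-mechanism classification: tandem arrays, collinear (segmental)
# blocks, transposable-element structural detection, retrogenes, and the
# per-gene mechanism summary.

# Karlin-Altschul parameters for gapped BLOSUM62 11/1 (BLAST defaults).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local protein alignment with BLOSUM62
#'
#' Smith-Waterman with affine gaps (a gap of length k costs
#' `gap_open + k * gap_extend`). Identity and query coverage come from the
#' traceback; the E-value is Karlin-Altschul with the standard gapped
#' BLOSUM62 constants.
#'
#' @param a,b protein sequences (query, subject).
#' @param gap_open,gap_extend gap penalties (BLAST 11/1 defaults).
#' @return list with `score`, `identity` (% identical aligned columns),
#'   `query_coverage` (aligned query span / query length), `aln_len`,
#'   `e_value`, and 1-based endpoints `q_start`,`q_end`,`s_start`,`s_end`.
#' @export
local_align_proteins <- function(a, b, gap_open = 11, gap_extend = 1) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  chars <- unique(strsplit(paste0(a, b), "")[[1]])
  if (!all(chars %in% c(AA_ALPHABET, "X", "*")))
    stop("non-amino-acid characters in input: ",
         paste(setdiff(chars, c(AA_ALPHABET, "X", "*")), collapse = ""))
  al <- .sw_pair_align(aa_encode(a), aa_encode(b), blosum62_matrix(),
                       gap_open, gap_extend)
  list(score = al$score,
       identity = if (al$aln_len > 0) 100 * al$n_ident / al$aln_len else 0,
       query_coverage = if (al$aln_len > 0)
         (al$a_end - al$a_start + 1) / nchar(a) else 0,
       aln_len = al$aln_len,
       e_value = KA_K * nchar(a) * nchar(b) * exp(-KA_LAMBDA * al$score),
       q_start = al$a_start, q_end = al$a_end,
       s_start = al$b_start, s_end = al$b_end)
}

#' Detect tandemly duplicated family members
#'
#' Within-family gene pairs on the same chromosome are tandem when all four
#' criteria hold: (1) the local alignment covers at least `min_coverage` of
#' the shorter protein; (2) identity is at least `min_identity` percent;
#' (3) the genes are at most `max_intervening` genes apart; and (4) the
#' pair lies within the genome-class distance window (100 kb for compact
#' genomes, 350 kb otherwise), measured as the genomic span from the start
#' of the upstream gene to the end of the downstream gene. Qualifying pairs
#' are merged into arrays by single linkage.
#'
#' @param family_genes character vector of family member gene ids.
#' @param annotation a [genome_annotation()].
#' @param min_coverage,min_identity,max_intervening criteria thresholds.
#' @param window distance window in bp; default chosen by the annotation's
#'   genome class (compact 1e5, standard 3.5e5).
#' @return list of tandem arrays; each is a list with `chromosome`,
#'   `member_ids` (ordered by start) and the supporting `pairs` table.
#' @seealso [tandem_pair_decision()] for the bare four-criteria decision.
#' @export
detect_tandem_arrays <- function(family_genes, annotation,
                                 min_coverage = 0.3, min_identity = 70,
                                 max_intervening = 10, window = NULL) {
  if (is.null(window))
    window <- if (annotation$genome_class == "compact") 1e5 else 3.5e5
  family_genes <- sort(unique(family_genes))
  has_prot <- family_genes %in% names(annotation$protein) &
    !is.na(annotation$protein[family_genes])
  if (any(!has_prot))
    warning("genes without protein excluded: ",
            paste(family_genes[!has_prot], collapse = ", "))
  family_genes <- family_genes[has_prot]
  g <- annotation$genes[family_genes, , drop = FALSE]
  pairs <- list()
  parent <- setNames(family_genes, family_genes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (chr in unique(g$chromosome)) {
    ids <- family_genes[g$chromosome == chr]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      ga <- g[a, ]; gb <- g[b, ]
      n_between <- abs(ga$rank - gb$rank) - 1
      span <- max(ga$end, gb$end) - min(ga$start, gb$start) + 1
      if (!tandem_pair_decision(NA, NA, n_between, span,
                                min_coverage = -Inf, min_identity = -Inf,
                                max_intervening = max_intervening,
                                window = window)) next
      pa <- annotation$protein[[a]]; pb <- annotation$protein[[b]]
      q <- if (nchar(pa) <= nchar(pb)) c(pa, pb) else c(pb, pa)
      al <- local_align_proteins(q[1], q[2])
      if (!tandem_pair_decision(al$identity, al$query_coverage, n_between,
                                span, min_coverage, min_identity,
                                max_intervening, window)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, identity = al$identity,
        coverage = al$query_coverage, n_intervening = n_between,
        span_bp = span, stringsAsFactors = FALSE)
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  if (length(pairs) == 0) return(list())
  pairs <- do.call(rbind, pairs)
  comp <- vapply(family_genes, find, character(1))
  arrays <- list()
  for (cc in unique(comp)) {
    members <- family_genes[comp == cc]
    if (length(members) < 2) next
    members <- members[order(g[members, "start"])]
    chr <- g[members[1], "chromosome"]
    arrays[[length(arrays) + 1L]] <- list(
      chromosome = chr, member_ids = members,
      genome_class = annotation$genome_class,
      pairs = pairs[pairs$gene_a %in% members | pairs$gene_b %in% members, ,
                    drop = FALSE])
  }
  ord <- order(vapply(arrays, function(a) a$member_ids[1], character(1)))
  arrays[ord]
}

#' The four tandem-pair criteria as a bare decision
#'
#' TRUE when the pair (1) aligns over at least `min_coverage` of the
#' shorter protein, (2) with identity of at least `min_identity` percent,
#' (3) lies at most `max_intervening` genes apart, and (4) spans at most
#' `window` bp. This is the decision applied by
#' [detect_tandem_arrays()]; exposed so the rule boundaries can be
#' exercised directly.
#'
#' @param identity percent identity of the aligned pair.
#' @param coverage aligned fraction of the shorter protein.
#' @param n_intervening genes between the pair on the chromosome.
#' @param span_bp genomic span from the upstream gene's start to the
#'   downstream gene's end.
#' @param min_coverage,min_identity,max_intervening,window thresholds.
#' @return logical.
#' @export
tandem_pair_decision <- function(identity, coverage, n_intervening,
                                 span_bp, min_coverage = 0.3,
                                 min_identity = 70, max_intervening = 10,
                                 window = 3.5e5) {
  isTRUE(coverage >= min_coverage || min_coverage == -Inf) &&
    isTRUE(identity >= min_identity || min_identity == -Inf) &&
    n_intervening <= max_intervening &&
    span_bp <= window
}

#' Chain collinear anchor pairs into segmental blocks
#'
#' Dynamic-programming best chains over homologous gene pairs (anchors)
#' ordered by chromosome rank, DAGchainer style. Chain score is the sum of
#' anchor scores minus `gap_penalty` per skipped rank unit; transitions
#' with a rank gap above `max_gap` on either chromosome are disallowed.
#' Both orientations (rank-increasing and rank-decreasing on the second
#' chromosome) are tried; chains are extracted best-first without anchor
#' reuse and reported when they have at least `min_pairs` anchors.
#'
#' @param anchor_pairs data.frame `gene_a`, `gene_b`, `score` of similarity
#'   pairs passing the E-value cutoff.
#' @param annotation_a,annotation_b annotations providing the ranks
#'   (may be the same object for intra-genome comparison).
#' @param min_pairs minimum anchors per reported block.
#' @param gap_penalty per skipped rank unit.
#' @param max_gap maximum rank gap between consecutive anchors.
#' @return list of blocks: `chrom_a`, `chrom_b`, `anchors` (data.frame),
#'   `chain_score`, `n_pairs`, `orientation`.
#' @export
chain_collinear_blocks <- function(anchor_pairs, annotation_a, annotation_b,
                                   min_pairs = 5, gap_penalty = 1.0,
                                   max_gap = 10) {
  if (nrow(anchor_pairs) == 0) return(list())
  unknown <- !(anchor_pairs$gene_a %in% rownames(annotation_a$genes)) |
    !(anchor_pairs$gene_b %in% rownames(annotation_b$genes))
  if (any(unknown))
    stop("anchors reference unknown genes: ",
         paste(anchor_pairs$gene_a[unknown], collapse = ", "))
  ga <- annotation_a$genes[anchor_pairs$gene_a, ]
  gb <- annotation_b$genes[anchor_pairs$gene_b, ]
  anchor_pairs$chrom_a <- ga$chromosome; anchor_pairs$rank_a <- ga$rank
  anchor_pairs$chrom_b <- gb$chromosome; anchor_pairs$rank_b <- gb$rank
  blocks <- list()
  for (key in unique(paste(anchor_pairs$chrom_a, anchor_pairs$chrom_b))) {
    sel <- paste(anchor_pairs$chrom_a, anchor_pairs$chrom_b) == key
    sub <- anchor_pairs[sel, , drop = FALSE]
    for (orient in c(1, -1)) {
      av <- sub
      av$rb <- orient * av$rank_b
      av <- av[order(av$rank_a, av$rb), , drop = FALSE]
      used <- rep(FALSE, nrow(av))
      repeat {
        res <- best_chain_dp(av[!used, , drop = FALSE], gap_penalty, max_gap)
        if (is.null(res) || length(res$chain) < min_pairs) break
        idx_all <- which(!used)[res$chain]
        anchors <- av[idx_all, c("gene_a", "gene_b", "score", "rank_a",
                                 "rank_b"), drop = FALSE]
        blocks[[length(blocks) + 1L]] <- list(
          chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
          anchors = anchors, chain_score = res$score,
          n_pairs = nrow(anchors),
          orientation = if (orient == 1) "same" else "inverted")
        used[idx_all] <- TRUE
        if (all(used)) break
      }
    }
  }
  # drop duplicate blocks found in both orientations (all-equal ranks) and
  # order deterministically by score
  if (length(blocks) > 1) {
    sig <- vapply(blocks, function(b)
      paste(sort(paste(b$anchors$gene_a, b$anchors$gene_b)), collapse = "|"),
      character(1))
    blocks <- blocks[!duplicated(sig)]
  }
  ord <- order(-vapply(blocks, `[[`, numeric(1), "chain_score"),
               vapply(blocks, function(b) b$anchors$gene_a[1], character(1)))
  blocks[ord]
}

# Best-scoring chain (strictly increasing rank_a and rb) via DP.
# Returns indices into the supplied frame plus the chain score.
best_chain_dp <- function(av, gap_penalty, max_gap) {
  n <- nrow(av)
  if (n == 0) return(NULL)
  score <- av$score
  best <- score
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      da <- av$rank_a[j] - av$rank_a[i]
      db <- av$rb[j] - av$rb[i]
      if (da <= 0 || db <= 0) next
      if (da > max_gap || db > max_gap) next
      cand <- best[i] + score[j] - gap_penalty * ((da - 1) + (db - 1))
      if (cand > best[j] + 1e-12) { best[j] <- cand; prev[j] <- i }
    }
  }
  end <- which.max(best)
  chain <- integer(); k <- end
  while (k != 0) { chain <- c(k, chain); k <- prev[k] }
  list(chain = chain, score = best[end])
}

#' Classify family genes as segmentally duplicated
#'
#' A gene is segmental when it is an anchor of a reported collinear block
#' or lies inside a block's genomic span (the convex hull of its anchors'
#' coordinates extended by `flank_bp`).
#'
#' @param family_genes gene ids to classify.
#' @param blocks output of [chain_collinear_blocks()].
#' @param annotation the [genome_annotation()] the genes belong to.
#' @param flank_bp extension of the block hull, matching the 50-kb windows
#'   the block search is run on.
#' @return character vector of segmental gene ids.
#' @export
classify_segmental <- function(family_genes, blocks, annotation,
                               flank_bp = 50000) {
  if (length(blocks) == 0) return(character())
  out <- character()
  g <- annotation$genes
  for (gene in family_genes) {
    hit <- FALSE
    for (b in blocks) {
      if (gene %in% b$anchors$gene_a || gene %in% b$anchors$gene_b) {
        hit <- TRUE; break
      }
      for (side in c("a", "b")) {
        ids <- b$anchors[[paste0("gene_", side)]]
        ids <- ids[ids %in% rownames(g)]
        if (length(ids) == 0) next
        chr <- g[ids[1], "chromosome"]
        if (g[gene, "chromosome"] != chr) next
        lo <- min(g[ids, "start"]) - flank_bp
        hi <- max(g[ids, "end"]) + flank_bp
        if (g[gene, "start"] >= lo && g[gene, "end"] <= hi) { hit <- TRUE }
      }
      if (hit) break
    }
    if (hit) out <- c(out, gene)
  }
  out
}

#' Classify which part of the parent gene a TE-carried copy duplicates
#'
#' The carried copy's protein is aligned to the parent protein; the aligned
#' span on the parent, as a fraction of parent length, decides the type:
#' type 1 (whole) touches both termini, type 2 only the 3' terminus, type 3
#' only the 5' terminus, type 4 (middle) neither. "Touching" a terminus
#' means reaching into its first/last `terminus_frac` of the parent.
#'
#' @param gene,parent_gene gene models (see [gene_model()]) with protein
#'   sequences; `gene` must overlap `element`'s span.
#' @param element a TE annotation (list with `chromosome`, `start`, `end`).
#' @param terminus_frac fraction of the parent defining each terminus.
#' @return integer fragment type in 1..4 with a descriptive
#'   `label` attribute.
#' @export
classify_te_carried_fragment <- function(gene, element, parent_gene,
                                         terminus_frac = 0.1) {
  if (gene$chromosome != element$chromosome ||
      gene$end < element$start || gene$start > element$end)
    stop("gene does not overlap the element span")
  al <- local_align_proteins(gene$protein_seq, parent_gene$protein_seq)
  plen <- nchar(parent_gene$protein_seq)
  f_start <- (al$s_start - 1) / plen
  f_end <- al$s_end / plen
  touch5 <- f_start <= terminus_frac
  touch3 <- f_end >= 1 - terminus_frac
  type <- if (touch5 && touch3) 1L else if (touch3) 2L else
    if (touch5) 3L else 4L
  structure(type, label = c("whole", "three_prime", "five_prime",
                            "middle")[type])
}

#' Detect retrogene candidates in a family
#'
#' Single-exon family members whose best multi-exon family paralog passes
#' the identity and coverage thresholds are reported as retrogenes
#' (intron-less copies arising by reverse transcription), with
#' `introns_lost` equal to the parent's exon count minus one.
#'
#' @param family_genes family member gene ids.
#' @param annotation a [genome_annotation()].
#' @param min_identity percent identity threshold.
#' @param min_coverage query-coverage threshold (of the candidate).
#' @return data.frame `retro_id`, `parent_id`, `identity`, `coverage`,
#'   `introns_lost`.
#' @export
detect_retrogenes <- function(family_genes, annotation, min_identity = 50,
                              min_coverage = 0.7) {
  g <- annotation$genes[family_genes, , drop = FALSE]
  single <- family_genes[g$n_exons == 1]
  multi <- family_genes[g$n_exons >= 2]
  rows <- list()
  for (s in single) {
    ps <- annotation$protein[[s]]
    if (is.null(ps) || is.na(ps)) next
    best <- NULL
    for (m in multi) {
      pm <- annotation$protein[[m]]
      if (is.null(pm) || is.na(pm)) next
      al <- local_align_proteins(ps, pm)
      if (is.null(best) || al$score > best$al$score)
        best <- list(id = m, al = al)
    }
    if (is.null(best)) next
    if (best$al$identity >= min_identity &&
        best$al$query_coverage >= min_coverage) {
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = s, parent_id = best$id,
        identity = best$al$identity, coverage = best$al$query_coverage,
        introns_lost = g[best$id, "n_exons"] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), parent_id = character(),
               identity = numeric(), coverage = numeric(),
               introns_lost = integer())
}

#' Summarize expansion mechanisms per gene and per family
#'
#' Mechanism labels are multi-valued (a gene can be TE-carried *and* sit in
#' a segmentally duplicated block); no precedence is imposed.
#'
#' @param assignments family assignments ([assign_families()] output).
#' @param tandem_arrays output of [detect_tandem_arrays()] (per family,
#'   concatenated).
#' @param segmental_ids character vector from [classify_segmental()].
#' @param te_calls data.frame `gene_id`, `element_class` for TE-carried
#'   genes (may be empty).
#' @param retro_calls output of [detect_retrogenes()].
#' @return list with `gene_labels` (gene, family, comma-joined labels) and
#'   `summary` (family x mechanism counts and percentages).
#' @export
summarize_mechanisms <- function(assignments, tandem_arrays = list(),
                                 segmental_ids = character(),
                                 te_calls = NULL, retro_calls = NULL) {
  tandem_ids <- unique(unlist(lapply(tandem_arrays, `[[`, "member_ids")))
  te_ids <- if (!is.null(te_calls) && nrow(te_calls)) te_calls$gene_id else
    character()
  retro_ids <- if (!is.null(retro_calls) && nrow(retro_calls))
    retro_calls$retro_id else character()
  labels <- lapply(assignments$gene_id, function(g) {
    l <- character()
    if (g %in% tandem_ids) l <- c(l, "tandem")
    if (g %in% segmental_ids) l <- c(l, "segmental")
    if (g %in% te_ids) l <- c(l, "TE")
    if (g %in% retro_ids) l <- c(l, "retro")
    if (length(l) == 0) "none" else paste(l, collapse = ",")
  })
  gene_labels <- data.frame(gene_id = assignments$gene_id,
                            family = assignments$family,
                            mechanisms = unlist(labels),
                            stringsAsFactors = FALSE)
  mechs <- c("tandem", "segmental", "TE", "retro", "none")
  rows <- list()
  for (fam in sort(unique(gene_labels$family))) {
    sub <- gene_labels[gene_labels$family == fam, ]
    n <- nrow(sub)
    for (m in mechs) {
      cnt <- sum(vapply(strsplit(sub$mechanisms, ","), function(x) m %in% x,
                        logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, mechanism = m, n_genes = cnt,
        percent = 100 * cnt / n, stringsAsFactors = FALSE)
    }
  }
  list(gene_labels = gene_labels, summary = do.call(rbind, rows))
}
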