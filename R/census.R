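# Family census: profile construction from seed alignments, local profile
# scanning with an empirical E-value null, and the domain-combination rules
# that define the four sucrose-metabolism families.

FAMILY_DOMAINS <- list(
  SuSy  = "PF00862",
  SPS   = c("PF00534", "PF05116"),
  SPP   = "PF05116",
  UDPGP = "PF01704")

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Consensus columns are alignment columns with fewer than 50% gaps.
#' Per-column scores are log-odds in half-bit units,
#' `2 * log2(p_a / bg_a)`, where `p_a` mixes observed counts with
#' background-proportional pseudocounts (total pseudocount mass
#' `20 * pseudocount`).
#'
#' @param seed_alignment aligned amino-acid sequences of equal length
#'   (named character vector or `AAStringSet`); at least 2.
#' @param background_freqs optional named background frequencies over the 20
#'   residues; defaults to Robinson-Robinson.
#' @param profile_id identifier stored with the profile (e.g. a Pfam
#'   accession).
#' @param gap_open,gap_extend non-negative gap penalties used when the
#'   profile is scanned.
#' @param pseudocount per-residue pseudocount weight (Laplace alpha).
#' @return An object of class `domain_profile`.
#' @export
build_domain_profile <- function(seed_alignment, background_freqs = NULL,
                                 profile_id = "profile", gap_open = 10,
                                 gap_extend = 1, pseudocount = 0.5) {
  seqs <- toupper(as_named_chr(seed_alignment))
  if (length(seqs) < 2) stop("need at least 2 seed sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("seed sequences are not aligned (unequal lengths)")
  bg <- if (is.null(background_freqs)) ROBINSON_FREQS else
    background_freqs[AA_ALPHABET]
  bg <- bg / sum(bg)
  mat <- do.call(rbind, strsplit(seqs, ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0) stop("all columns are >= 50% gaps")
  pssm <- matrix(0, length(keep), 20)
  consensus <- character(length(keep))
  A <- 20 * pseudocount
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    col <- col[col %in% AA_ALPHABET]
    n <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(n) + A * bg) / (length(col) + A)
    pssm[k, ] <- 2 * log2(p / bg)
    consensus[k] <- AA_ALPHABET[which.max(pssm[k, ])]
  }
  structure(list(profile_id = profile_id, pssm = pssm,
                 consensus = paste(consensus, collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend,
                 n_seed = length(seqs), background = bg),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("domain_profile", x$profile_id, "-", nrow(x$pssm), "columns from",
      x$n_seed, "seed sequences\n")
  invisible(x)
}

#' Scan a proteome with a domain profile
#'
#' Local profile-sequence alignment (position-specific match scores, affine
#' gaps). Significance comes from an empirical per-sequence null: each
#' protein is shuffled `n_shuffle` times, a Gumbel distribution is fitted to
#' the decoy scores by the method of moments, and the E-value is the Gumbel
#' tail probability times the number of proteins scanned.
#'
#' The scan is staged for speed, as production profile searches are: a
#' small pilot null (`n_prefilter` shuffles) screens out sequences whose
#' score is clearly unremarkable, and the full `n_shuffle` null is fitted
#' only for candidates within `prefilter_factor` of the reporting cutoff.
#'
#' @param profile a [build_domain_profile()] object.
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param e_init report hits with E-value at or below this (search cutoff).
#' @param n_shuffle decoys per sequence for the null fit.
#' @param n_prefilter pilot decoys per sequence.
#' @param prefilter_factor candidates with pilot E-value below
#'   `prefilter_factor * e_init` get the full null.
#' @param seed integer seed; the scan is deterministic given it.
#' @return data.frame of hits sorted by E-value: `gene_id`, `profile_id`,
#'   `bit_score`, `e_value`, `prot_start`, `prot_end`, `profile_coverage`.
#' @export
scan_proteins <- function(profile, proteins, e_init = 1.0, n_shuffle = 200,
                          n_prefilter = 32, prefilter_factor = 50,
                          seed = 1) {
  stopifnot(inherits(profile, "domain_profile"))
  prots <- as_named_chr(proteins)
  if (length(prots) == 0) stop("empty proteome")
  ids <- names(prots)
  if (is.null(ids)) ids <- paste0("seq", seq_along(prots))
  empty <- !nzchar(prots) | is.na(prots)
  if (any(empty)) {
    warning(sum(empty), " empty protein(s) skipped")
    prots <- prots[!empty]; ids <- ids[!empty]
  }
  n_target <- length(prots)
  M <- nrow(profile$pssm)
  gumbel_e <- function(null_scores, score) {
    scale <- sd(null_scores) * sqrt(6) / pi
    if (!is.finite(scale) || scale <= 0) scale <- 1e-6
    loc <- mean(null_scores) - 0.57721566 * scale
    p <- 1 - exp(-exp(-(score - loc) / scale))
    p * n_target
  }
  rows <- vector("list", n_target)
  for (i in seq_len(n_target)) {
    enc <- aa_encode(prots[i])
    score <- .sw_profile_score(profile$pssm, enc, profile$gap_open,
                               profile$gap_extend)
    set.seed(child_seed(seed, i))
    n1 <- min(n_prefilter, n_shuffle)
    decoys <- lapply(seq_len(n1), function(k) sample(enc))
    e_value <- gumbel_e(.sw_profile_score_many(profile$pssm, decoys,
                                               profile$gap_open,
                                               profile$gap_extend), score)
    if (e_value > prefilter_factor * e_init || n1 == n_shuffle) {
      # pilot estimate is final (either clearly insignificant or the
      # requested null size was already reached)
    } else {
      decoys <- lapply(seq_len(n_shuffle), function(k) sample(enc))
      e_value <- gumbel_e(.sw_profile_score_many(profile$pssm, decoys,
                                                 profile$gap_open,
                                                 profile$gap_extend), score)
    }
    if (e_value <= e_init) {
      al <- .sw_profile_align(profile$pssm, enc, profile$gap_open,
                              profile$gap_extend)
      rows[[i]] <- data.frame(
        gene_id = ids[i], profile_id = profile$profile_id,
        bit_score = score, e_value = e_value,
        prot_start = al$seq_start, prot_end = al$seq_end,
        profile_coverage = (al$prof_end - al$prof_start + 1) / M,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), profile_id = character(),
                      bit_score = numeric(), e_value = numeric(),
                      prot_start = integer(), prot_end = integer(),
                      profile_coverage = numeric())
  out[order(out$e_value, out$gene_id), , drop = FALSE]
}

#' Assign genes to families from confirmed domain hits
#'
#' Retains hits with E-value at or below `e_confirm` and applies the
#' domain-combination rules: SuSy requires PF00862; UDPGP requires PF01704;
#' SPS requires both PF00534 and PF05116; SPP requires PF05116 without a
#' confirming PF00534 hit. A gene matching the defining domains of two
#' different families is assigned to the family whose best hit has the
#' lower E-value, and the conflict is recorded in the `conflicts` attribute.
#'
#' @param hits data.frame of domain hits ([scan_proteins()] or
#'   [read_domtbl()] output, possibly concatenated over profiles).
#' @param e_confirm confirmation E-value cutoff.
#' @return data.frame with one row per gene that received a family:
#'   `gene_id`, `family`, `best_e`, `coverage`, `status`. Genes with no
#'   confirmed hits are omitted (family `none`).
#' @export
assign_families <- function(hits, e_confirm = 0.01) {
  h <- hits[hits$e_value <= e_confirm, , drop = FALSE]
  h <- h[order(h$gene_id, h$profile_id, h$e_value), , drop = FALSE]
  out <- list(); conflicts <- character()
  for (g in sort(unique(h$gene_id))) {
    hg <- h[h$gene_id == g, , drop = FALSE]
    doms <- unique(hg$profile_id)
    cand <- character()
    if ("PF00862" %in% doms) cand <- c(cand, "SuSy")
    if ("PF01704" %in% doms) cand <- c(cand, "UDPGP")
    if (all(c("PF00534", "PF05116") %in% doms)) cand <- c(cand, "SPS")
    else if ("PF05116" %in% doms) cand <- c(cand, "SPP")
    if (length(cand) == 0) next
    best_e_of <- vapply(cand, function(fam) {
      min(hg$e_value[hg$profile_id %in% FAMILY_DOMAINS[[fam]]])
    }, numeric(1))
    fam <- cand[order(best_e_of, cand)][1]
    if (length(cand) > 1)
      conflicts <- c(conflicts,
                     paste0(g, ": ", paste(cand, collapse = "/"),
                            " -> ", fam))
    sup <- hg[hg$profile_id %in% FAMILY_DOMAINS[[fam]], , drop = FALSE]
    best <- sup[which.min(sup$e_value), ]
    out[[g]] <- data.frame(gene_id = g, family = fam,
                           best_e = best$e_value,
                           coverage = best$profile_coverage,
                           status = "full", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), family = character(),
               best_e = numeric(), coverage = numeric(),
               status = character())
  rownames(res) <- NULL
  attr(res, "conflicts") <- conflicts
  res
}

#' Flag family members with partial domains and no expression evidence
#'
#' Members whose best hit covers less than `min_coverage` of the profile
#' *and* that carry no expression evidence are set to status
#' `partial_excluded` (they are retained in the table but dropped from
#' phylogenetic and codon analyses downstream). Either condition alone
#' keeps a gene.
#'
#' @param assignments output of [assign_families()].
#' @param expression_evidence character vector of gene ids with expression
#'   support.
#' @param min_coverage minimum profile coverage counted as a full domain.
#' @return The assignments with updated `status`.
#' @export
flag_partial_members <- function(assignments, expression_evidence = character(),
                                 min_coverage = 0.7) {
  part <- assignments$coverage < min_coverage &
    !(assignments$gene_id %in% expression_evidence)
  assignments$status <- ifelse(part, "partial_excluded", "full")
  assignments
}
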