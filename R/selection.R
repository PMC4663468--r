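# Codon-level selection analysis: back-translation of protein alignments,
# the pair filters, and pairwise Ka/Ks (NG86 counting with a
# YN00-compatible weighted mode).

GENETIC_CODE_TBL <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

sense_codons <- function() {
  gc <- GENETIC_CODE_TBL()
  names(gc)[gc != "*"]
}

codon_aa <- function(codon) unname(GENETIC_CODE_TBL()[codon])

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Expands each aligned protein row to codons using the gene's CDS: gaps
#' become `---` and each residue is replaced by its source codon. Every
#' residue must agree with the translation of its CDS (a terminal stop on
#' the CDS is tolerated); mismatches are an error naming the residue.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   sequences (equal lengths, `-` gaps).
#' @param cds_by_id named character vector of CDS sequences.
#' @return object of class `codon_alignment`: named character vector of
#'   aligned codon strings (each `3 * n_columns` long).
#' @export
backtranslate <- function(protein_alignment, cds_by_id) {
  prots <- toupper(as_named_chr(protein_alignment))
  ids <- names(prots)
  if (is.null(ids)) stop("protein alignment must be named")
  if (length(unique(nchar(prots))) != 1) stop("alignment rows differ in length")
  out <- character(length(prots))
  for (k in seq_along(prots)) {
    id <- ids[k]
    cds <- cds_by_id[[id]]
    if (is.null(cds) || is.na(cds)) stop("no CDS for ", id)
    if (nchar(cds) %% 3 != 0) stop("CDS length of ", id,
                                   " is not a multiple of 3")
    codons <- split_codons(toupper(cds))
    aas <- codon_aa(codons)
    if (length(aas) > 0 && aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    res <- strsplit(prots[k], "")[[1]]
    nongap <- which(res != "-")
    if (length(nongap) != length(codons))
      stop("CDS of ", id, " encodes ", length(codons),
           " residues but alignment row has ", length(nongap))
    mism <- which(aas != res[nongap])
    if (length(mism) > 0)
      stop("translation mismatch for ", id, " at residue ", mism[1],
           " (", aas[mism[1]], " vs ", res[nongap[mism[1]]], ")")
    row <- rep("---", length(res))
    row[nongap] <- codons
    out[k] <- paste(row, collapse = "")
  }
  structure(setNames(out, ids), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x), "sequences x", nchar(x[[1]]) / 3,
      "codon columns\n")
  invisible(x)
}

#' Apply the pair filters for Ka/Ks estimation
#'
#' A two-sequence codon alignment is rejected when the ungapped overlap is
#' 150 bp or shorter, or when nucleotide identity over the overlap is below
#' 70%.
#'
#' @param pair two-sequence `codon_alignment` (or character vector of two
#'   aligned codon strings).
#' @param min_overlap_bp minimum ungapped overlap (exclusive bound).
#' @param min_identity minimum nucleotide identity over the overlap (0-1).
#' @return list with `accept` (logical) and `reason` (`NA`, `"length"` or
#'   `"identity"`).
#' @export
filter_pair_alignment <- function(pair, min_overlap_bp = 150,
                                  min_identity = 0.7) {
  stopifnot(length(pair) == 2)
  c1 <- split_codons(pair[[1]]); c2 <- split_codons(pair[[2]])
  keep <- c1 != "---" & c2 != "---"
  overlap_bp <- 3 * sum(keep)
  if (overlap_bp <= min_overlap_bp)
    return(list(accept = FALSE, reason = "length"))
  a <- strsplit(paste(c1[keep], collapse = ""), "")[[1]]
  b <- strsplit(paste(c2[keep], collapse = ""), "")[[1]]
  ident <- mean(a == b)
  if (ident < min_identity)
    return(list(accept = FALSE, reason = "identity"))
  list(accept = TRUE, reason = NA_character_)
}

# --- NG86 machinery -------------------------------------------------------

# Per-codon synonymous site fractions; changes to stop codons are excluded
# from the denominator so each position contributes one full site.
ng86_sites_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- GENETIC_CODE_TBL()
    sc <- sense_codons()
    S <- setNames(numeric(length(sc)), sc)
    for (c0 in sc) {
      bases <- strsplit(c0, "")[[1]]
      s <- 0
      for (k in 1:3) {
        alts <- setdiff(DNA_BASES, bases[k])
        n_syn <- 0L; n_valid <- 0L
        for (a in alts) {
          b2 <- bases; b2[k] <- a
          c2 <- paste(b2, collapse = "")
          if (gc[[c2]] == "*") next
          n_valid <- n_valid + 1L
          if (gc[[c2]] == gc[[c0]]) n_syn <- n_syn + 1L
        }
        s <- s + if (n_valid > 0) n_syn / n_valid else 0
      }
      S[c0] <- s
    }
    cache <<- S
    cache
  }
})

# Average synonymous/nonsynonymous differences between two sense codons,
# averaging over all orderings of the differing positions; pathways through
# stop codons are excluded (renormalized), falling back to all pathways if
# none is stop-free. Optional per-step weights (kappa/frequency) for the
# YN00-compatible mode.
ng86_path_diff <- function(c1, c2, step_weight = NULL) {
  gc <- GENETIC_CODE_TBL()
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else if (d == 2)
    list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) pos[o])
  eval_path <- function(order) {
    cur <- b1; sd <- 0; nd <- 0; w <- 1; valid <- TRUE
    for (k in order) {
      nxt <- cur; nxt[k] <- b2[k]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*") valid <- FALSE
      if (!is.null(step_weight))
        w <- w * step_weight(cur[k], b2[k], k)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid, w = w)
  }
  paths <- lapply(perms, eval_path)
  valid <- vapply(paths, `[[`, logical(1), "valid")
  if (any(valid)) paths <- paths[valid]
  w <- vapply(paths, `[[`, numeric(1), "w")
  if (sum(w) <= 0) w <- rep(1, length(paths))
  w <- w / sum(w)
  c(sd = sum(w * vapply(paths, `[[`, numeric(1), "sd")),
    nd = sum(w * vapply(paths, `[[`, numeric(1), "nd")))
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("saturated: proportion of differences ", round(p, 3),
                      " >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

# kappa (ts/tv rate ratio) from third-codon-position differences, K80-style.
estimate_kappa <- function(c1, c2) {
  t1 <- substring(c1, 3, 3); t2 <- substring(c2, 3, 3)
  diff <- t1 != t2
  if (!any(diff)) return(2)
  ts <- mapply(is_transition, t1[diff], t2[diff])
  P <- sum(ts) / length(t1); Q <- sum(!ts) / length(t1)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(2)
  a <- -0.5 * log(w1) + 0.25 * log(w2)
  b <- -0.5 * log(w2)
  if (b <= 0) return(2)
  max(2 * a / b, 0.1)
}

#' Pairwise Ka/Ks estimation
#'
#' NG86 counting: fractional synonymous/nonsynonymous sites per codon
#' (stop-leading changes excluded, so sites sum to three per codon),
#' differences averaged over all orderings of multi-position pathways with
#' stop-traversing pathways excluded, and Jukes-Cantor correction of the
#' proportions. The YN00-compatible mode weights site counts and pathway
#' steps by a transition/transversion ratio estimated from the data (K80,
#' third positions) and position-specific target-base frequencies (F3x4).
#' Codon columns containing a gap or an ambiguous base in either sequence
#' are dropped pairwise; observed stop codons are a hard error.
#'
#' @param pair two-sequence `codon_alignment` (or character vector of two
#'   codon strings).
#' @param method `"NG86"` or `"YN00"`.
#' @return object of class `kaks_result`: list with `ka`, `ks`, `ratio`
#'   (`NA` when `ks` is 0), `S`, `N`, `Sd`, `Nd`, `n_codons`, `method`.
#' @export
kaks_pair <- function(pair, method = c("NG86", "YN00")) {
  method <- match.arg(method)
  stopifnot(length(pair) == 2)
  c1 <- split_codons(toupper(pair[[1]]))
  c2 <- split_codons(toupper(pair[[2]]))
  if (length(c1) != length(c2)) stop("aligned codon strings differ in length")
  clean <- function(x) grepl("^[ACGT]{3}$", x)
  keep <- clean(c1) & clean(c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (length(c1) == 0) stop("no comparable codon columns")
  gc <- GENETIC_CODE_TBL()
  if (any(gc[c1] == "*") || any(gc[c2] == "*"))
    stop("internal stop codon in observed sequence")
  kappa <- NULL; basefreq <- NULL
  step_weight <- NULL; site_weight <- NULL
  if (method == "YN00") {
    kappa <- estimate_kappa(c1, c2)
    nt <- rbind(do.call(rbind, strsplit(c1, "")),
                do.call(rbind, strsplit(c2, "")))
    basefreq <- lapply(1:3, function(k) {
      f <- table(factor(nt[, k], levels = DNA_BASES))
      p <- (as.numeric(f) + 0.1) / (sum(f) + 0.4)
      setNames(p, DNA_BASES)
    })
    step_weight <- function(from, to, k)
      (if (is_transition(from, to)) kappa else 1) * basefreq[[k]][[to]]
  }
  count_sites <- function(codon) {
    if (method == "NG86") return(ng86_sites_table()[[codon]])
    bases <- strsplit(codon, "")[[1]]
    s <- 0
    for (k in 1:3) {
      alts <- setdiff(DNA_BASES, bases[k])
      wsyn <- 0; wtot <- 0
      for (a in alts) {
        b2 <- bases; b2[k] <- a
        cc <- paste(b2, collapse = "")
        if (gc[[cc]] == "*") next
        w <- (if (is_transition(bases[k], a)) kappa else 1) *
          basefreq[[k]][[a]]
        wtot <- wtot + w
        if (gc[[cc]] == gc[[codon]]) wsyn <- wsyn + w
      }
      s <- s + if (wtot > 0) wsyn / wtot else 0
    }
    s
  }
  S1 <- vapply(c1, count_sites, numeric(1))
  S2 <- vapply(c2, count_sites, numeric(1))
  S <- (sum(S1) + sum(S2)) / 2
  N <- 3 * length(c1) - S
  diffs <- mapply(function(a, b) ng86_path_diff(a, b, step_weight), c1, c2)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc_correct(pS); ka <- jc_correct(pN)
  structure(list(ka = ka, ks = ks,
                 ratio = if (ks > 0) ka / ks else NA_real_,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codons = length(c1), method = method,
                 kappa = kappa),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("kaks_result (%s): Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%d codons)\n",
              x$method, x$ka, x$ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              x$n_codons))
  invisible(x)
}
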