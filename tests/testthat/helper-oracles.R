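# Independent oracles used by the property and acceptance tests. These are
# deliberately written against the method definitions from first
# principles, not by calling the package internals they check.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

# NG86 sites and pathway-enumerated differences for a pair of aligned
# codon vectors. Site fractions: per position, synonymous fraction among
# single-base changes that do not create a stop. Differences: enumerate
# every ordering of the differing positions explicitly, discard orderings
# whose intermediate codons are stops (keep all if none survives), and
# average the per-step synonymous/nonsynonymous counts.
oracle_ng86 <- function(codons1, codons2) {
  site_s <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    total <- 0
    for (k in 1:3) {
      syn <- 0; valid <- 0
      for (alt in setdiff(ORACLE_BASES, b[k])) {
        b2 <- b; b2[k] <- alt
        cc <- paste(b2, collapse = "")
        if (ORACLE_CODE[[cc]] == "*") next
        valid <- valid + 1
        if (ORACLE_CODE[[cc]] == ORACLE_CODE[[codon]]) syn <- syn + 1
      }
      total <- total + if (valid > 0) syn / valid else 0
    }
    total
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_orders(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  pair_diff <- function(ca, cb) {
    ba <- strsplit(ca, "")[[1]]; bb <- strsplit(cb, "")[[1]]
    pos <- which(ba != bb)
    if (length(pos) == 0) return(c(0, 0))
    paths <- list()
    for (ord in all_orders(pos)) {
      cur <- ba; sd <- 0; nd <- 0; ok <- TRUE
      for (k in ord) {
        nxt <- cur; nxt[k] <- bb[k]
        a1 <- ORACLE_CODE[[paste(cur, collapse = "")]]
        a2 <- ORACLE_CODE[[paste(nxt, collapse = "")]]
        if (a2 == "*") ok <- FALSE
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths[[length(paths) + 1]] <- list(sd = sd, nd = nd, ok = ok)
    }
    kept <- Filter(function(p) p$ok, paths)
    if (length(kept) == 0) kept <- paths
    c(mean(vapply(kept, `[[`, numeric(1), "sd")),
      mean(vapply(kept, `[[`, numeric(1), "nd")))
  }
  S <- (sum(vapply(codons1, site_s, numeric(1))) +
          sum(vapply(codons2, site_s, numeric(1)))) / 2
  d <- mapply(pair_diff, codons1, codons2)
  list(S = S, N = 3 * length(codons1) - S,
       Sd = sum(d[1, ]), Nd = sum(d[2, ]))
}

# Exhaustive best-chain search: every subset of anchors, kept if strictly
# increasing in both rank coordinates with rank gaps at most max_gap,
# scored as anchor scores minus gap_penalty per skipped rank unit.
oracle_best_chain <- function(rank_a, rank_b, score, gap_penalty = 1,
                              max_gap = 10) {
  n <- length(rank_a)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(rank_a[idx])]
    ra <- rank_a[idx]; rb <- rank_b[idx]
    if (any(duplicated(ra)) || any(diff(rb) <= 0)) next
    if (length(idx) > 1 &&
        (any(diff(ra) > max_gap) | any(diff(rb) > max_gap) |
         any(diff(ra) <= 0))) next
    s <- sum(score[idx])
    if (length(idx) > 1)
      s <- s - gap_penalty * sum((diff(ra) - 1) + (diff(rb) - 1))
    if (s > best) best <- s
  }
  best
}

# Exhaustive local alignment: every increasing matching of residue subsets
# of a and b, scored with the substitution matrix and affine gaps
# (gap of length k between consecutive matched pairs costs
# gap_open + k * gap_ext per sequence). The empty alignment scores 0.
oracle_local_align <- function(a, b, submat, alphabet, gap_open = 11,
                               gap_ext = 1) {
  av <- match(strsplit(a, "")[[1]], alphabet)
  bv <- match(strsplit(b, "")[[1]], alphabet)
  n <- length(av); m <- length(bv)
  gap_cost <- function(k) if (k > 0) gap_open + gap_ext * k else 0
  best <- 0
  subsets <- function(n) {
    out <- list()
    for (mask in 1:(2^n - 1))
      out[[length(out) + 1]] <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    out
  }
  sa <- subsets(n); sb <- subsets(m)
  by_size_b <- split(sb, lengths(sb))
  for (ia in sa) {
    k <- length(ia)
    for (ib in by_size_b[[as.character(k)]] %||% list()) {
      s <- sum(submat[cbind(av[ia], bv[ib])])
      if (k > 1)
        s <- s - sum(vapply(seq_len(k - 1), function(t)
          gap_cost(ia[t + 1] - ia[t] - 1) + gap_cost(ib[t + 1] - ib[t] - 1),
          numeric(1)))
      if (s > best) best <- s
    }
  }
  best
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Direct-summation codon site likelihood for a rooted 3-taxon tree
# ((A:t1,B:t2):t3,C:t4): sum over both internal states explicitly, with
# transition probabilities from a series-expansion matrix exponential
# (Matrix::expm), uniform root frequencies over the 61 sense codons.
oracle_site_loglik_3taxa <- function(codA, codB, codC, t1, t2, t3, t4,
                                     kappa, omega) {
  sc <- ORACLE_SENSE
  nsc <- length(sc)
  is_ts <- function(x, y) (x %in% c("A", "G")) == (y %in% c("A", "G")) &&
    x != y && ((x %in% c("A", "G") && y %in% c("A", "G")) ||
               (x %in% c("C", "T") && y %in% c("C", "T")))
  Q <- matrix(0, nsc, nsc, dimnames = list(sc, sc))
  ref <- matrix(0, nsc, nsc)
  for (i in seq_len(nsc)) for (j in seq_len(nsc)) {
    if (i == j) next
    bi <- strsplit(sc[i], "")[[1]]; bj <- strsplit(sc[j], "")[[1]]
    dif <- which(bi != bj)
    if (length(dif) != 1) next
    ts <- (bi[dif] %in% c("A", "G")) == (bj[dif] %in% c("A", "G"))
    syn <- ORACLE_CODE[[sc[i]]] == ORACLE_CODE[[sc[j]]]
    r <- if (ts) kappa else 1
    ref[i, j] <- r
    Q[i, j] <- if (syn) r else omega * r
  }
  diag(Q) <- -rowSums(Q)
  rate_ref <- mean(rowSums(ref))
  Q <- Q / rate_ref
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  P1 <- P(t1); P2 <- P(t2); P3 <- P(t3); P4 <- P(t4)
  iA <- match(codA, sc); iB <- match(codB, sc); iC <- match(codC, sc)
  total <- 0
  for (u in seq_len(nsc)) for (v in seq_len(nsc)) {
    total <- total + (1 / nsc) * P3[u, v] * P1[v, iA] * P2[v, iB] *
      P4[u, iC]
  }
  log(total)
}

# random sense-codon pair with at most `max_diff` differing positions per
# codon (used for the NG86 oracle comparison)
random_codon_pair <- function(n_codons, max_diff = 2) {
  c1 <- sample(ORACLE_SENSE, n_codons, replace = TRUE)
  c2 <- vapply(c1, function(cd) {
    repeat {
      b <- strsplit(cd, "")[[1]]
      nd <- sample(0:max_diff, 1)
      if (nd > 0) {
        pos <- sample(1:3, nd)
        for (k in pos) b[k] <- sample(setdiff(ORACLE_BASES, b[k]), 1)
      }
      out <- paste(b, collapse = "")
      if (ORACLE_CODE[[out]] != "*") return(out)
    }
  }, character(1))
  list(c1 = c1, c2 = unname(c2))
}
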