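# Sitewise selection scan: a simplified Muse-Gaut-style codon model with a
# single transition/transversion ratio, uniform codon frequencies and one
# omega per site, maximized per codon column and tested against omega = 1
# by a likelihood-ratio test on chi-square(1).

# Codon-state bookkeeping (61 sense codons), cached.
codon_space <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- sense_codons()
    gc <- GENETIC_CODE_TBL()
    n <- length(sc)
    syn_ts <- matrix(0, n, n); syn_tv <- matrix(0, n, n)
    ns_ts <- matrix(0, n, n); ns_tv <- matrix(0, n, n)
    bl <- strsplit(sc, "")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dif <- which(bl[[i]] != bl[[j]])
      if (length(dif) != 1) next
      ts <- is_transition(bl[[i]][dif], bl[[j]][dif])
      syn <- gc[[sc[i]]] == gc[[sc[j]]]
      m <- if (syn && ts) "syn_ts" else if (syn) "syn_tv" else
        if (ts) "ns_ts" else "ns_tv"
      if (m == "syn_ts") { syn_ts[i, j] <- syn_ts[j, i] <- 1 }
      if (m == "syn_tv") { syn_tv[i, j] <- syn_tv[j, i] <- 1 }
      if (m == "ns_ts") { ns_ts[i, j] <- ns_ts[j, i] <- 1 }
      if (m == "ns_tv") { ns_tv[i, j] <- ns_tv[j, i] <- 1 }
    }
    cache <<- list(codons = sc, syn_ts = syn_ts, syn_tv = syn_tv,
                   ns_ts = ns_ts, ns_tv = ns_tv)
    cache
  }
})

# Symmetric rate matrix (uniform codon frequencies): relative rate kappa
# for transitions, omega for nonsynonymous changes. Normalized by the
# neutral (omega = 1) rate constant, so branch lengths are expected
# substitutions per site at omega = 1 and sites under positive selection
# evolve proportionally faster, purifying sites slower.
codon_rate_matrix <- function(kappa, omega) {
  cs <- codon_space()
  syn <- kappa * cs$syn_ts + cs$syn_tv
  ns <- kappa * cs$ns_ts + cs$ns_tv
  Q <- syn + omega * ns
  diag(Q) <- -rowSums(Q)
  rate_ref <- mean(rowSums(syn + ns))
  if (rate_ref <= 0) rate_ref <- 1e-12
  Q / rate_ref
}

codon_eigen <- function(kappa, omega) {
  e <- eigen(codon_rate_matrix(kappa, omega), symmetric = TRUE)
  list(U = e$vectors, lambda = e$values)
}

codon_pmat <- function(eg, t) {
  P <- eg$U %*% (exp(eg$lambda * t) * t(eg$U))
  P[P < 0] <- 0
  P
}

# Tip index matrix (taxa x sites) from a codon alignment; NA for gaps or
# ambiguous codons.
codon_index_matrix <- function(codon_aln) {
  sc <- sense_codons()
  rows <- lapply(as.character(codon_aln), function(s) {
    cods <- split_codons(toupper(s))
    idx <- match(cods, sc)
    bad <- is.na(idx) & grepl("^[ACGT]{3}$", cods)
    if (any(bad)) stop("stop codon in observed sequence")
    idx
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(codon_aln)
  m
}

# Per-site log-likelihood via Felsenstein pruning, vectorized over sites.
# `tipidx` is taxa x sites; `tree` an ape phylo whose tips match its rows;
# branch lengths are tree$edge.length * scale.
sitewise_loglik <- function(tipidx, tree, kappa, omega, scale = 1,
                            eg = NULL) {
  if (is.null(eg)) eg <- codon_eigen(kappa, omega)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  S <- ncol(tipidx); n_state <- length(eg$lambda)
  ord <- match(tree$tip.label, rownames(tipidx))
  if (anyNA(ord)) stop("tree tips not found in alignment")
  L <- vector("list", nn)
  for (i in seq_len(ntip)) {
    M <- matrix(0, n_state, S)
    idx <- tipidx[ord[i], ]
    known <- !is.na(idx)
    M[cbind(idx[known], which(known))] <- 1
    if (any(!known)) M[, !known] <- 1
    L[[i]] <- M
  }
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    P <- codon_pmat(eg, tree$edge.length[e] * scale)
    contrib <- P %*% L[[chi]]
    L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
  }
  root <- ntip + 1L
  lik <- colMeans(L[[root]])
  log(pmax(lik, 1e-300))
}

#' Sitewise selection scan over a codon alignment
#'
#' Two stages. Globally, the transition/transversion ratio and a branch
#' scale factor are estimated together with a single alignment-wide omega
#' by maximum likelihood (Felsenstein pruning over the 61 sense codons).
#' Per site, the likelihood is then maximized over omega in
#' `[0, omega_max]` (shared omega-grid evaluation followed by
#' golden-section refinement to |d omega| <= `tol`) and compared against
#' the omega = 1 constraint by a likelihood-ratio test on chi-square with
#' one degree of freedom; no boundary mixture correction is applied, which
#' is conservative for the positive tail. Sites with omega above 1 and
#' p below `alpha` are classified `positive`; below 1, `purifying`;
#' otherwise `neutral`. All-gap sites are reported untested.
#'
#' @param codon_aln a `codon_alignment` (>= 3 sequences).
#' @param tree `phylo` with tip labels matching the alignment; branch
#'   lengths are used as given (times the estimated scale), or set to 0.1
#'   before scaling when absent.
#' @param alpha significance level for classification.
#' @param omega_max upper bound of the omega search.
#' @param tol absolute tolerance of the omega refinement.
#' @return data.frame with one row per codon site: `site`, `omega_hat`,
#'   `lnl_hat`, `lnl_neutral`, `lrt_stat`, `p_value`, `class`, `tested`.
#' @export
sitewise_selection_scan <- function(codon_aln, tree, alpha = 0.05,
                                    omega_max = 50, tol = 1e-4) {
  if (length(codon_aln) < 3) stop("need at least 3 sequences")
  tipidx <- codon_index_matrix(codon_aln)
  S_all <- ncol(tipidx)
  tested <- colSums(!is.na(tipidx)) >= 2
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1,
                                                         nrow(tree$edge))
  sub <- tipidx[, tested, drop = FALSE]

  nll <- function(par) {
    kappa <- exp(par[1]); scale <- exp(par[2]); omega <- exp(par[3])
    ll <- sum(sitewise_loglik(sub, tree, kappa, omega, scale))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- optim(log(c(2, 1, 0.5)), nll, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  kappa <- exp(fit$par[1]); scale <- exp(fit$par[2])

  # stage 2: shared omega grid, vectorized over sites
  grid <- sort(unique(c(0, exp(seq(log(0.005), log(omega_max),
                                   length.out = 28)), 1)))
  gl <- matrix(-Inf, length(grid), ncol(sub))
  for (k in seq_along(grid))
    gl[k, ] <- sitewise_loglik(sub, tree, kappa, grid[k], scale)
  i_neutral <- which(grid == 1)

  memo <- new.env(parent = emptyenv())
  site_ll <- function(omega, col) {
    key <- sprintf("%.10g", omega)
    eg <- get0(key, envir = memo)
    if (is.null(eg)) {
      eg <- codon_eigen(kappa, omega)
      assign(key, eg, envir = memo)
    }
    sitewise_loglik(sub[, col, drop = FALSE], tree, kappa, omega, scale,
                    eg = eg)
  }
  phi <- (sqrt(5) - 1) / 2
  golden <- function(lo, hi, col) {
    x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
    f1 <- site_ll(x1, col); f2 <- site_ll(x2, col)
    while (hi - lo > tol) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + phi * (hi - lo); f2 <- site_ll(x2, col)
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - phi * (hi - lo); f1 <- site_ll(x1, col)
      }
    }
    x <- (lo + hi) / 2
    list(omega = x, lnl = site_ll(x, col))
  }

  n_sub <- ncol(sub)
  omega_hat <- lnl_hat <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    k <- which.max(gl[, s])
    lo <- grid[max(k - 1, 1)]; hi <- grid[min(k + 1, length(grid))]
    ref <- golden(lo, hi, s)
    if (ref$lnl >= gl[k, s]) {
      omega_hat[s] <- ref$omega; lnl_hat[s] <- ref$lnl
    } else {
      omega_hat[s] <- grid[k]; lnl_hat[s] <- gl[k, s]
    }
  }
  lnl_neutral <- gl[i_neutral, ]
  lrt <- pmax(2 * (lnl_hat - lnl_neutral), 0)
  pval <- 1 - pchisq(lrt, df = 1)
  cls <- ifelse(pval < alpha & omega_hat > 1, "positive",
                ifelse(pval < alpha & omega_hat < 1, "purifying", "neutral"))

  out <- data.frame(site = seq_len(S_all), omega_hat = NA_real_,
                    lnl_hat = NA_real_, lnl_neutral = NA_real_,
                    lrt_stat = NA_real_, p_value = NA_real_,
                    class = "untested", tested = tested,
                    stringsAsFactors = FALSE)
  out$omega_hat[tested] <- omega_hat
  out$lnl_hat[tested] <- lnl_hat
  out$lnl_neutral[tested] <- lnl_neutral
  out$lrt_stat[tested] <- lrt
  out$p_value[tested] <- pval
  out$class[tested] <- cls
  attr(out, "kappa") <- kappa
  attr(out, "scale") <- scale
  out
}
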