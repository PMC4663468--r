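# Synthetic-evolution simulator: gene-family birth/loss histories along a
# species tree with labeled duplication mechanisms, codon sequence
# evolution under per-site omega classes, and planted expression
# divergence. Genome layout and TE planting live in simulate-genome.R.

#' Default simulation configuration
#'
#' The defaults define the study conditions used throughout the test
#' suite: a four-species tree with dated divergences, purifying-dominated
#' codon evolution, and mechanism mix/fragment-type probabilities matching
#' the observed contributions of tandem/segmental/TE/retro expansion (the
#' fragment-type split is 40/17.1/28.6/14.3).
#'
#' @param species_tree Newick string with branch lengths.
#' @param birth_rates named numeric: per-gene birth rates (events per
#'   branch-length unit) for `tandem`, `segmental`, `TE`, `retro`.
#' @param loss_rate per-gene loss rate.
#' @param te_class_probs named probabilities over TE classes.
#' @param fragment_probs probabilities of carried-fragment types 1-4.
#' @param kappa transition/transversion rate ratio.
#' @param omega_classes data.frame with `prop` and `omega` columns
#'   (per-site omega classes; proportions sum to 1).
#' @param gene_codons length of the seed gene in codons.
#' @param domain_range codon range occupied by the diagnostic domain.
#' @param n_exons exon count of the seed gene.
#' @param tissues,replicates expression design.
#' @param divergence_prob probability a recent paralog pair gets planted
#'   expression divergence.
#' @param effect_size planted shift on the normalized log2 scale.
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param gc intergenic GC content.
#' @param n_filler filler (non-family) genes per species genome.
#' @param gene_spacing mean intergenic spacing in bp.
#' @param max_family abort threshold on family size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species_tree = "((A:0.30,B:0.30)AB:0.20,(C:0.35,D:0.35)CD:0.15)ABCD;",
                       birth_rates = c(tandem = 0.8, segmental = 0.4,
                                       TE = 0.4, retro = 0.25),
                       loss_rate = 0,
                       te_class_probs = c(LTR = 1/3, Helitron = 1/3,
                                          CACTA = 1/3),
                       fragment_probs = c(0.40, 0.171, 0.286, 0.143),
                       kappa = 2,
                       omega_classes = data.frame(
                         prop = c(0.6, 0.35, 0.05),
                         omega = c(0.1, 0.5, 1.0)),
                       gene_codons = 160,
                       domain_range = c(31, 130),
                       n_exons = 4,
                       tissues = 16, replicates = 3,
                       divergence_prob = 0.5, effect_size = 2,
                       noise_sd = 0.5,
                       gc = 0.4, n_filler = 30, gene_spacing = 6000,
                       max_family = 10000) {
  stopifnot(all(birth_rates >= 0), loss_rate >= 0,
            abs(sum(omega_classes$prop) - 1) < 1e-8,
            all(omega_classes$omega >= 0))
  fragment_probs <- fragment_probs / sum(fragment_probs)
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic seed alignment for a protein domain
#'
#' Generates a domain family: a random consensus and `n_seed` seed
#' sequences derived from it by point substitutions, as input for
#' [build_domain_profile()] and as the domain planted by the simulator.
#'
#' @param length_aa consensus length.
#' @param n_seed number of seed sequences.
#' @param mut_prob per-residue substitution probability in each seed.
#' @param seed integer seed.
#' @return list with `consensus` and named `alignment`.
#' @export
make_domain_seed <- function(length_aa = 100, n_seed = 8, mut_prob = 0.12,
                             seed = 1) {
  set.seed(seed)
  cons <- sample(AA_ALPHABET, length_aa, replace = TRUE,
                 prob = ROBINSON_FREQS)
  aln <- vapply(seq_len(n_seed), function(k) {
    s <- cons
    mut <- runif(length_aa) < mut_prob
    s[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(aln) <- paste0("seed", seq_len(n_seed))
  list(consensus = paste(cons, collapse = ""), alignment = aln)
}

#' Simulate a gene-family history along the species tree
#'
#' Gillespie birth/loss along each species-tree branch: each live gene
#' lineage gains copies at the configured per-mechanism rates and is lost
#' at `loss_rate`. Mechanism, TE class and carried-fragment type are drawn
#' per event and recorded. At each species divergence every live lineage
#' speciates into both daughters; the number of live lineages at that
#' instant is the true ancestral (MRCA) copy count. For a single starting
#' gene and total birth rate b, the expected number of birth events on a
#' branch of length T is `exp(b*T) - 1`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `truth_log`: species tree, gene-lineage node
#'   table, event list, extant gene table and true MRCA counts per
#'   internal species node.
#' @export
simulate_family_history <- function(config, seed = 1) {
  st <- ape::read.tree(text = config$species_tree)
  if (is.null(st$node.label) || any(!nzchar(st$node.label)))
    st$node.label <- make_species_node_labels(st)
  depths <- ape::node.depth.edgelength(st)
  b_rates <- config$birth_rates[config$birth_rates > 0]
  b_tot <- sum(b_rates)
  if (b_tot > 0) {
    total_len <- sum(st$edge.length)
    if (expm1(b_tot * total_len) > config$max_family)
      stop("expected family size exceeds max_family; lower the birth rates")
  }
  set.seed(seed)
  env <- new.env()
  env$nodes <- list()
  env$events <- list()
  env$extant <- list()
  env$mrca <- list()
  env$counter <- 0L
  new_node <- function(parent, time, kind, mechanism = NA_character_,
                       te_class = NA_character_, fragment = NA_integer_,
                       species = NA_character_, label = NA_character_) {
    env$counter <- env$counter + 1L
    id <- env$counter
    env$nodes[[id]] <- list(id = id, parent = parent, time = time,
                            kind = kind, mechanism = mechanism,
                            te_class = te_class, fragment = fragment,
                            species = species, label = label)
    id
  }
  ntip <- length(st$tip.label)
  root <- ntip + 1L
  sp_label <- function(v) if (v <= ntip) st$tip.label[v] else
    st$node.label[v - ntip]

  walk_edge <- function(sp_child, t0, live) {
    # live: data.frame(open = gene node ids, mech/te/frag of pending copy)
    e <- which(st$edge[, 2] == sp_child)
    T <- st$edge.length[e]
    t <- 0
    while (nrow(live) > 0) {
      rate <- nrow(live) * (b_tot + config$loss_rate)
      if (rate <= 0) break
      dt <- rexp(1, rate)
      if (t + dt > T) break
      t <- t + dt
      gi <- sample.int(nrow(live), 1)
      p_loss <- config$loss_rate / (b_tot + config$loss_rate)
      if (runif(1) < p_loss) {
        live <- live[-gi, , drop = FALSE]
        next
      }
      mech <- sample(names(b_rates), 1, prob = b_rates)
      tec <- NA_character_; frag <- NA_integer_
      if (mech == "TE") {
        tec <- sample(names(config$te_class_probs), 1,
                      prob = config$te_class_probs)
        frag <- sample(1:4, 1, prob = config$fragment_probs)
      }
      d <- new_node(live$open[gi], t0 + t, "duplication", mechanism = mech,
                    te_class = tec, fragment = frag)
      orig <- new_node(d, t0 + t, "dup_orig")
      copy <- new_node(d, t0 + t, "dup_copy", mechanism = mech,
                       te_class = tec, fragment = frag)
      env$events[[length(env$events) + 1L]] <- data.frame(
        time = t0 + t, species_edge = sp_label(sp_child), mechanism = mech,
        te_class = tec, fragment = frag, parent_node = live$open[gi],
        child_node = copy, stringsAsFactors = FALSE)
      # original copy keeps its provenance, new copy records the mechanism
      live <- rbind(live,
                    data.frame(open = copy, origin = mech, te_class = tec,
                               fragment = frag, stringsAsFactors = FALSE))
      live$open[gi] <- orig
      if (nrow(live) > config$max_family)
        stop("family size exceeded max_family during simulation")
    }
    t_end <- t0 + T
    if (sp_child <= ntip) {
      sp <- st$tip.label[sp_child]
      for (k in seq_len(nrow(live))) {
        gid <- sprintf("%s_g%03d", sp, length(env$extant) + 1L)
        leaf <- new_node(live$open[k], t_end, "leaf", species = sp,
                         label = gid,
                         mechanism = live$origin[k],
                         te_class = live$te_class[k],
                         fragment = live$fragment[k])
        env$extant[[length(env$extant) + 1L]] <- data.frame(
          gene_id = gid, species = sp, node = leaf,
          origin = live$origin[k], te_class = live$te_class[k],
          fragment = live$fragment[k], stringsAsFactors = FALSE)
      }
    } else {
      lbl <- sp_label(sp_child)
      env$mrca[[lbl]] <- nrow(live)
      # one speciation node per lineage; both daughter branches descend
      # from it so shared ancestral segments are evolved exactly once
      live2 <- live
      for (k in seq_len(nrow(live)))
        live2$open[k] <- new_node(live$open[k], t_end, "speciation")
      for (child in st$edge[st$edge[, 1] == sp_child, 2])
        walk_edge(child, t_end, live2)
    }
  }

  root_gene <- new_node(0L, 0, "root")
  env$mrca[[sp_label(root)]] <- 1L
  live0 <- data.frame(open = root_gene, origin = "ancestral",
                      te_class = NA_character_, fragment = NA_integer_,
                      stringsAsFactors = FALSE)
  for (child in st$edge[st$edge[, 1] == root, 2])
    walk_edge(child, depths[root], live0)

  nodes <- do.call(rbind, lapply(env$nodes, function(n)
    data.frame(n, stringsAsFactors = FALSE)))
  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(time = numeric(), species_edge = character(),
               mechanism = character(), te_class = character(),
               fragment = integer(), parent_node = integer(),
               child_node = integer())
  extant <- if (length(env$extant)) do.call(rbind, env$extant) else
    stop("no extant genes (all lineages lost); raise rates or lower loss")
  structure(list(config = config, species_tree = st, nodes = nodes,
                 events = events, extant = extant,
                 mrca_counts = unlist(env$mrca), seed = seed),
            class = "truth_log")
}

make_species_node_labels <- function(st) {
  ntip <- length(st$tip.label)
  vapply(seq_len(st$Nnode), function(k) {
    tips <- ape::extract.clade(st, ntip + k)$tip.label
    paste(sort(tips), collapse = "")
  }, character(1))
}

#' @export
print.truth_log <- function(x, ...) {
  cat("truth_log:", nrow(x$extant), "extant genes in",
      length(unique(x$extant$species)), "species;",
      nrow(x$events), "birth events\n")
  invisible(x)
}

#' Extract the extant gene tree from a truth log
#'
#' Builds the rooted gene tree over extant genes (branch lengths in
#' species-tree time units), suppressing pass-through nodes left by lost
#' lineages, together with the gene -> species map.
#'
#' @param truth a `truth_log`.
#' @return list with `tree` (`phylo`) and `species_map`.
#' @export
gene_tree_phylo <- function(truth) {
  nodes <- truth$nodes
  children <- split(nodes$id, nodes$parent)
  # keep only nodes with extant descendants (children have larger ids than
  # their parent, so decreasing id order is a reverse topological order)
  keep <- logical(nrow(nodes))
  for (i in rev(seq_len(nrow(nodes)))) {
    n <- nodes[i, ]
    if (n$kind == "leaf") keep[n$id] <- TRUE
    else {
      kids <- children[[as.character(n$id)]]
      keep[n$id] <- any(keep[kids])
    }
  }
  newick_of <- function(id) {
    n <- nodes[id, ]
    kids <- children[[as.character(id)]]
    kids <- kids[keep[kids]]
    if (n$kind == "leaf") return(list(str = n$label, time = n$time))
    subs <- lapply(kids, newick_of)
    if (length(subs) == 1) return(subs[[1]])  # pass-through node: splice
    parts <- vapply(subs, function(s)
      paste0(s$str, ":", format(max(s$time - n$time, 0), digits = 10)),
      character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"), time = n$time)
  }
  roots <- nodes$id[nodes$parent == 0 & keep[nodes$id]]
  res <- newick_of(roots[1])
  tree <- ape::read.tree(text = paste0(res$str, ";"))
  sp <- setNames(truth$extant$species, truth$extant$gene_id)
  list(tree = tree, species_map = sp)
}

# -- codon sequence evolution ---------------------------------------------

random_sense_codons <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

aa_to_codon <- function(aa) {
  gc <- GENETIC_CODE_TBL()
  vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- names(gc)[gc == a]
    if (length(opts) == 0) stop("no codon for residue ", a)
    sample(opts, 1)
  }, character(1))
}

#' Evolve codon sequences along the simulated gene lineages
#'
#' The seed gene is `gene_codons` long with the domain consensus
#' back-translated into its `domain_range`; sites are assigned omega
#' classes by the configured proportions and evolve by a continuous-time
#' codon substitution process (transition/transversion ratio kappa,
#' per-site omega) restricted to sense codons, so no stop codons arise.
#' TE duplications of fragment types 2-4 truncate the new copy to the
#' carried portion of the parent (3' region, 5' region, or middle).
#'
#' @param truth a `truth_log`.
#' @param config the [sim_config()] used to build it.
#' @param seed integer seed.
#' @param domain optional [make_domain_seed()] result; generated from
#'   `seed` when absent.
#' @return list with `cds` and `protein` (named by extant gene),
#'   `site_classes` (omega class per seed-gene codon), `domain`,
#'   `fragments` (codon ranges kept by truncated copies) and
#'   `domain_frac` (per extant gene, the fraction of the domain region
#'   still present after fragment truncation).
#' @export
evolve_codon_sequences <- function(truth, config, seed = 1, domain = NULL) {
  if (is.null(domain))
    domain <- make_domain_seed(config$domain_range[2] -
                                 config$domain_range[1] + 1,
                               seed = child_seed(seed, 991))
  set.seed(seed)
  L <- config$gene_codons
  dr <- config$domain_range
  root_codons <- random_sense_codons(L)
  root_codons[dr[1]:dr[2]] <- aa_to_codon(domain$consensus)
  classes <- sample.int(nrow(config$omega_classes), L, replace = TRUE,
                        prob = config$omega_classes$prop)
  sc <- sense_codons()
  eigens <- lapply(config$omega_classes$omega, function(w)
    codon_eigen(config$kappa, w))
  evolve_branch <- function(codon_idx, cls, t) {
    if (t <= 0) return(codon_idx)
    out <- codon_idx
    for (ci in unique(cls)) {
      P <- codon_pmat(eigens[[ci]], t)
      sel <- which(cls == ci & !is.na(codon_idx))
      for (s in sel)
        out[s] <- sample.int(length(sc), 1, prob = P[codon_idx[s], ])
    }
    out
  }
  nodes <- truth$nodes
  children <- split(nodes$id, nodes$parent)
  fragments <- list()
  cds <- character(); protein <- character()
  domain_frac <- numeric()
  recurse <- function(id, codon_idx, cls, t_parent) {
    n <- nodes[id, ]
    codon_idx <- evolve_branch(codon_idx, cls, n$time - t_parent)
    if (n$kind == "leaf") {
      codons <- sc[codon_idx[!is.na(codon_idx)]]
      s <- paste(codons, collapse = "")
      cds[[n$label]] <<- s
      protein[[n$label]] <<- codon_aa_string(codons)
      domain_frac[[n$label]] <<- mean(!is.na(codon_idx[dr[1]:dr[2]]))
      return(invisible())
    }
    kids <- children[[as.character(id)]]
    for (k in kids) {
      kk <- nodes[k, ]
      ci <- codon_idx; cl <- cls
      if (identical(kk$kind, "dup_copy") && !is.na(kk$mechanism) &&
          kk$mechanism == "TE" && !is.na(kk$fragment) && kk$fragment != 1) {
        keep_rng <- fragment_codon_range(kk$fragment, L)
        drop <- setdiff(seq_len(L), keep_rng)
        ci[drop] <- NA_integer_
        fragments[[as.character(k)]] <<- keep_rng
      }
      recurse(k, ci, cl, n$time)
    }
  }
  root_idx <- match(root_codons, sc)
  roots <- nodes$id[nodes$parent == 0]
  recurse(roots[1], root_idx, classes, 0)
  list(cds = cds, protein = protein, site_classes = classes,
       domain = domain, fragments = fragments,
       domain_frac = domain_frac,
       omega_by_site = config$omega_classes$omega[classes])
}

codon_aa_string <- function(codons) {
  paste(GENETIC_CODE_TBL()[codons], collapse = "")
}

fragment_codon_range <- function(type, L) {
  switch(type,
         stop("type 1 keeps the whole gene"),
         ceiling(0.60 * L):L,                       # 3' region
         1:floor(0.40 * L),                         # 5' region
         ceiling(0.20 * L):floor(0.70 * L))         # middle
}

# Fragment inheritance: a truncated copy's descendants keep the truncation
# (NA codons are never resurrected), matching the detector's view of a
# TE-carried partial gene.

#' Simulate a codon alignment along a tree with per-site omega
#'
#' Continuous-time codon substitution over the 61 sense codons (uniform
#' root frequencies) along a fixed tree, with an independent omega per
#' site. Used for calibrating the sitewise selection scan.
#'
#' @param tree `phylo` with branch lengths (expected substitutions per
#'   codon site).
#' @param site_omegas numeric vector, one omega per codon site.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return `codon_alignment` named by the tree's tip labels.
#' @export
simulate_codon_alignment <- function(tree, site_omegas, kappa = 2,
                                     seed = 1) {
  set.seed(seed)
  sc <- sense_codons()
  S <- length(site_omegas)
  eigens <- lapply(sort(unique(site_omegas)), function(w)
    codon_eigen(kappa, w))
  names(eigens) <- as.character(sort(unique(site_omegas)))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- matrix(NA_integer_, ntip + tree$Nnode, S)
  states[root, ] <- sample.int(length(sc), S, replace = TRUE)
  # preorder traversal: reorder edges so parents precede children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    for (w in names(eigens)) {
      sel <- which(site_omegas == as.numeric(w))
      P <- codon_pmat(eigens[[w]], t)
      for (s in sel)
        states[chi, s] <- sample.int(length(sc), 1,
                                     prob = P[states[par, s], ])
    }
  }
  aln <- vapply(seq_len(ntip), function(i)
    paste(sc[states[i, ]], collapse = ""), character(1))
  structure(setNames(aln, tree$tip.label), class = "codon_alignment")
}

#' Simulated expression matrix with planted divergence
#'
#' Gene-by-sample matrix on the raw scale (`2^x - 1` of a log2-normal
#' model). Baseline tissue profiles are shared within recent paralog
#' pairs; with probability `divergence_prob` a pair receives an additive
#' shift of `effect_size` in 1-3 random tissues for one member. Replicate
#' noise is Gaussian on the log2 scale.
#'
#' @param gene_ids genes to include (rows).
#' @param pairs data.frame `gene_a`,`gene_b` of paralog pairs considered
#'   for planted divergence (may be empty).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `matrix` (raw scale), `groups` (sample -> tissue) and
#'   `truth` (data.frame of planted divergent pairs and their tissues).
#' @export
simulate_expression <- function(gene_ids, pairs, config, seed = 1) {
  set.seed(seed)
  nt <- config$tissues; nr <- config$replicates
  samples <- paste0("T", rep(seq_len(nt), each = nr), "_r",
                    rep(seq_len(nr), nt))
  groups <- setNames(paste0("T", rep(seq_len(nt), each = nr)), samples)
  base <- matrix(rnorm(length(gene_ids) * nt, mean = 5, sd = 1.5),
                 length(gene_ids), nt, dimnames = list(gene_ids, NULL))
  shift <- matrix(0, length(gene_ids), nt, dimnames = list(gene_ids, NULL))
  truth <- list()
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
      if (!(a %in% gene_ids && b %in% gene_ids)) next
      base[b, ] <- base[a, ]           # shared profile within the pair
      if (runif(1) < config$divergence_prob) {
        tset <- sample.int(nt, sample(1:3, 1))
        shift[b, tset] <- shift[b, tset] + config$effect_size
        truth[[length(truth) + 1L]] <- data.frame(
          gene_a = a, gene_b = b,
          tissues = paste(paste0("T", sort(tset)), collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        truth[[length(truth) + 1L]] <- data.frame(
          gene_a = a, gene_b = b, tissues = "", stringsAsFactors = FALSE)
      }
    }
  }
  logm <- matrix(0, length(gene_ids), length(samples),
                 dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    ts <- as.integer(sub("_r.*", "", sub("T", "", samples[j])))
    logm[, j] <- base[, ts] + shift[, ts] +
      rnorm(length(gene_ids), 0, config$noise_sd)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_a = character(), gene_b = character(),
               tissues = character())
  list(matrix = pmax(2^logm - 1, 0), groups = groups, truth = truth)
}
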