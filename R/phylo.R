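# Gene trees, reconciliation against species trees, ancestral (MRCA) copy
# counts, and reciprocal best pairs.

#' Poisson-corrected distance matrix from a protein alignment
#'
#' Pairwise distances `d = -ln(1 - p)` with `p` the proportion of differing
#' columns among shared non-gap positions. Pairs with fewer than 30 shared
#' non-gap columns, or with `p` at saturation, are an error.
#'
#' @param alignment named character vector (or `AAStringSet`) of aligned
#'   sequences of equal length.
#' @param min_shared minimum shared non-gap columns per pair.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(alignment, min_shared = 30) {
  seqs <- toupper(as_named_chr(alignment))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1) stop("sequences are not aligned")
  mat <- do.call(rbind, strsplit(seqs, ""))
  isgap <- mat == "-" | mat == "."
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !isgap[i, ] & !isgap[j, ]
    ns <- sum(shared)
    if (ns < min_shared)
      stop("pair ", ids[i], " / ", ids[j], " shares only ", ns,
           " non-gap columns")
    p <- mean(mat[i, shared] != mat[j, shared])
    if (p >= 1 - 1e-9)
      stop("pair ", ids[i], " / ", ids[j], " is saturated (p = ", p, ")")
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining gene tree
#'
#' Canonical Saitou-Nei neighbor joining on a symmetric distance matrix,
#' with labels sorted first so that relabeled inputs give the identical
#' tree. Negative branch lengths are clamped to zero.
#'
#' @param dist symmetric distance matrix with row/column names (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (nrow(dist) < 3) stop("need at least 3 taxa")
  ord <- order(rownames(dist))
  dist <- dist[ord, ord, drop = FALSE]
  tr <- ape::nj(stats::as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Column-resamples the alignment `n_reps` times, rebuilds the NJ tree from
#' each replicate, and records for each internal edge of the point-estimate
#' tree the percentage of replicates containing the same bipartition.
#'
#' @param alignment as for [protein_distance_matrix()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the point-estimate tree with `node.label` set to percent support.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  seqs <- toupper(as_named_chr(alignment))
  point <- nj_tree(protein_distance_matrix(seqs))
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, ""))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(boot) <- names(seqs)
    reps[[r]] <- tryCatch(nj_tree(protein_distance_matrix(boot)),
                          error = function(e) NULL)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- round(100 * counts / length(reps))
  point
}

#' Root a gene tree to minimize implied duplications
#'
#' Tries every edge of the unrooted gene tree as a root, reconciles each
#' rooted candidate against the species tree, and keeps the rooting with
#' the fewest duplication nodes; ties go to the midpoint rooting.
#'
#' @param gene_tree `phylo`, rooted or unrooted.
#' @param species_tree rooted `phylo` of species.
#' @param species_map named character vector, gene id -> species.
#' @return a rooted `phylo`.
#' @export
root_min_dup <- function(gene_tree, species_tree, species_map) {
  un <- ape::unroot(gene_tree)
  tips <- un$tip.label
  cand <- list(); ndup <- numeric()
  for (e in seq_len(nrow(un$edge))) {
    child <- un$edge[e, 2]
    below <- if (child <= length(tips)) tips[child] else
      ape::extract.clade(un, child)$tip.label
    if (length(below) == 0 || length(below) == length(tips)) next
    rooted <- tryCatch(
      ape::root(un, outgroup = below, resolve.root = TRUE),
      error = function(err) NULL)
    if (is.null(rooted) || !ape::is.rooted(rooted)) next
    rec <- reconcile_lca(rooted, species_tree, species_map)
    key <- paste(sort(below), collapse = "|")
    if (!key %in% names(cand)) {
      cand[[key]] <- rooted
      ndup[key] <- sum(rec$events$event == "duplication")
    }
  }
  if (length(cand) == 0) return(gene_tree)
  best <- which(ndup == min(ndup))
  if (length(best) == 1) return(cand[[best]])
  mid <- tryCatch(phangorn::midpoint(un), error = function(e) NULL)
  if (!is.null(mid) && ape::is.rooted(mid)) mid else cand[[best[1]]]
}

#' Reconcile a rooted gene tree against a species tree by LCA mapping
#'
#' Each gene-tree node is mapped to the lowest species-tree node containing
#' the species of its descendant leaves. An internal node is a duplication
#' when its children's leaf-species sets intersect, otherwise a speciation.
#'
#' @param gene_tree rooted binary `phylo`; tip labels are gene ids.
#' @param species_tree rooted `phylo`; tip labels are species.
#' @param species_map named character vector, gene id -> species.
#' @return object of class `reconciled_tree`: the gene tree, an `events`
#'   data.frame (gene-tree node, mapped species-tree node label, event) and
#'   the species tree.
#' @export
reconcile_lca <- function(gene_tree, species_tree, species_map) {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  tips <- gene_tree$tip.label
  sp <- species_map[tips]
  if (anyNA(sp))
    stop("species tag missing for: ",
         paste(tips[is.na(sp)], collapse = ", "))
  if (!all(sp %in% species_tree$tip.label))
    stop("unknown species tag(s): ",
         paste(setdiff(sp, species_tree$tip.label), collapse = ", "))
  ntip <- length(tips)
  nnode <- gene_tree$Nnode
  # postorder species sets
  spsets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) spsets[[i]] <- sp[i]
  po <- ape::postorder(gene_tree)
  for (e in po) {
    par <- gene_tree$edge[e, 1]; chi <- gene_tree$edge[e, 2]
    spsets[[par]] <- union(spsets[[par]], spsets[[chi]])
  }
  sp_node <- function(set) {
    set <- unique(set)
    if (length(set) == 1) match(set, species_tree$tip.label)
    else ape::getMRCA(species_tree, set)
  }
  maps <- vapply(seq_len(ntip + nnode), function(v) sp_node(spsets[[v]]),
                 numeric(1))
  children <- split(gene_tree$edge[, 2], gene_tree$edge[, 1])
  events <- data.frame(node = seq_len(ntip + nnode),
                       species_node = maps,
                       event = NA_character_)
  for (v in (ntip + 1):(ntip + nnode)) {
    ch <- children[[as.character(v)]]
    sets <- lapply(ch, function(c) unique(spsets[[c]]))
    inter <- length(intersect(sets[[1]], sets[[2]])) > 0
    events$event[v] <- if (inter) "duplication" else "speciation"
  }
  events$event[seq_len(ntip)] <- "leaf"
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 events = events, species_map = species_map),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  ev <- x$events$event
  cat("reconciled_tree:", sum(ev == "leaf"), "genes;",
      sum(ev == "duplication"), "duplication and",
      sum(ev == "speciation"), "speciation nodes\n")
  invisible(x)
}

species_node_id <- function(species_tree, species_node) {
  if (is.numeric(species_node)) return(as.integer(species_node))
  if (length(species_node) > 1 ||
      grepl(",", species_node)) {
    tips <- if (length(species_node) > 1) species_node else
      strsplit(species_node, ",")[[1]]
    return(ape::getMRCA(species_tree, trimws(tips)))
  }
  hit <- match(species_node, species_tree$node.label)
  if (!is.na(hit)) return(length(species_tree$tip.label) + hit)
  hit <- match(species_node, species_tree$tip.label)
  if (!is.na(hit)) return(hit)
  stop("cannot resolve species node: ", species_node)
}

#' Ancestral copy count at a species-tree divergence
#'
#' Counts the gene lineages present at the instant of the given
#' species-tree divergence: speciation nodes of the reconciled gene tree
#' mapped exactly to that node, plus gene-tree edges whose parent maps
#' strictly above it and whose child maps strictly below it (lineages that
#' pass through the divergence without a recorded speciation). Inferred
#' losses are not counted, so the estimate is a lower bound when lineages
#' were lost.
#'
#' @param reconciled a [reconcile_lca()] result.
#' @param species_node internal node of the species tree: a node number, a
#'   node label, or a character vector (or comma-separated string) of
#'   species whose MRCA is taken.
#' @return integer copy count.
#' @export
mrca_copy_count <- function(reconciled, species_node) {
  st <- reconciled$species_tree
  s <- species_node_id(st, species_node)
  if (s <= length(st$tip.label))
    stop("species_node is a leaf; use the per-genome census instead")
  anc <- ancestors_of(st, s)         # strict ancestors of s
  below <- descendants_of(st, s)     # strict descendants of s
  ev <- reconciled$events
  n_spec <- sum(ev$event == "speciation" & ev$species_node == s)
  gt <- reconciled$gene_tree
  n_edge <- 0L
  for (e in seq_len(nrow(gt$edge))) {
    mu <- ev$species_node[gt$edge[e, 1]]
    mv <- ev$species_node[gt$edge[e, 2]]
    if (mu %in% anc && mv %in% below) n_edge <- n_edge + 1L
  }
  n_spec + n_edge
}

ancestors_of <- function(tree, node) {
  root <- length(tree$tip.label) + 1L
  out <- integer()
  while (node != root) {
    node <- tree$edge[tree$edge[, 2] == node, 1]
    out <- c(out, node)
  }
  out
}

descendants_of <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer()
  while (length(kids)) {
    out <- c(out, kids)
    kids <- tree$edge[tree$edge[, 1] %in% kids, 2]
  }
  out
}

#' Reciprocal best cross-group pairs
#'
#' For genes labeled with groups (e.g. monocot vs dicot), returns the pairs
#' `(a, b)` from different groups such that `b` is `a`'s nearest
#' cross-group neighbor and vice versa, by patristic distance when a tree
#' is supplied or by matrix distance otherwise. Ties are broken by label
#' order with a warning.
#'
#' @param tree_or_dist `phylo` tree or symmetric distance matrix.
#' @param group_labels named character vector, gene id -> group.
#' @return data.frame `gene_a`, `gene_b`, `distance`.
#' @export
reciprocal_best_pairs <- function(tree_or_dist, group_labels) {
  d <- if (inherits(tree_or_dist, "phylo"))
    ape::cophenetic.phylo(tree_or_dist) else as.matrix(tree_or_dist)
  ids <- rownames(d)
  grp <- group_labels[ids]
  if (length(unique(grp)) < 2) return(
    data.frame(gene_a = character(), gene_b = character(),
               distance = numeric()))
  nn <- setNames(rep(NA_character_, length(ids)), ids)
  for (i in ids) {
    others <- ids[grp != grp[i]]
    if (length(others) == 0) next
    dv <- d[i, others]
    best <- others[dv == min(dv)]
    if (length(best) > 1) {
      warning("tie for nearest cross-group neighbor of ", i,
              "; broken by label order")
      best <- sort(best)
    }
    nn[i] <- best[1]
  }
  rows <- list()
  for (i in ids) {
    j <- nn[[i]]
    if (is.na(j) || is.na(nn[[j]])) next
    if (nn[[j]] == i && i < j)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = i, gene_b = j, distance = d[i, j],
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               distance = numeric())
}
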