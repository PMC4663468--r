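# Expression normalization and paralog expression-divergence testing.

#' Normalize an expression matrix
#'
#' `log2(x + 1)` transform followed by per-gene median centering, so every
#' row has median zero. The centering step is idempotent; set
#' `log2_transform = FALSE` for data already on a log scale.
#'
#' @param mat non-negative numeric matrix, genes x samples.
#' @param log2_transform apply the log transform before centering.
#' @return matrix of the same shape with row medians zero.
#' @export
normalize_expression <- function(mat, log2_transform = TRUE) {
  mat <- as.matrix(mat)
  if (log2_transform) {
    if (any(mat < 0)) stop("negative expression values")
    mat <- log2(mat + 1)
  }
  sweep(mat, 1, apply(mat, 1, median))
}

#' Test expression divergence between two paralogs
#'
#' Per tissue, a two-sample t-test (Welch by default) compares the two
#' genes' normalized replicate values; tissues with p below `alpha` are
#' divergent, and the pair is divergent when at least one tissue is.
#' Tissues with fewer than two replicates are skipped with a warning. No
#' multiple-testing correction is applied across tissues by default;
#' `p_adjust = "BH"` enables Benjamini-Hochberg.
#'
#' @param gene_a,gene_b row names in `mat`.
#' @param mat normalized expression matrix (see [normalize_expression()]).
#' @param groups named character vector, sample (column) -> tissue.
#' @param alpha per-tissue significance level.
#' @param var_equal use the pooled-variance (classical Student) form.
#' @param p_adjust p-value adjustment method across tissues
#'   (`stats::p.adjust` codes; `"none"` default).
#' @return object of class `divergence_result`: per-tissue table plus
#'   `divergent_tissues` and `is_divergent`.
#' @export
paralog_divergence_test <- function(gene_a, gene_b, mat, groups,
                                    alpha = 0.05, var_equal = FALSE,
                                    p_adjust = "none") {
  if (!all(c(gene_a, gene_b) %in% rownames(mat)))
    stop("gene(s) missing from matrix: ",
         paste(setdiff(c(gene_a, gene_b), rownames(mat)), collapse = ", "))
  groups <- groups[colnames(mat)]
  tissues <- sort(unique(groups))
  rows <- list()
  for (ts in tissues) {
    cols <- which(groups == ts)
    if (length(cols) < 2) {
      warning("tissue ", ts, " has < 2 replicates; skipped")
      next
    }
    xa <- mat[gene_a, cols]; xb <- mat[gene_b, cols]
    if (sd(xa) == 0 && sd(xb) == 0) {
      rows[[ts]] <- data.frame(tissue = ts, mean_diff = mean(xa) - mean(xb),
                               t_stat = if (mean(xa) == mean(xb)) 0 else Inf,
                               p_value = if (mean(xa) == mean(xb)) 1 else 0,
                               stringsAsFactors = FALSE)
      next
    }
    tt <- t.test(xa, xb, var.equal = var_equal)
    rows[[ts]] <- data.frame(tissue = ts, mean_diff = mean(xa) - mean(xb),
                             t_stat = unname(tt$statistic),
                             p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_value <- p.adjust(tab$p_value, method = p_adjust)
  div <- tab$tissue[tab$p_value < alpha]
  structure(list(gene_a = gene_a, gene_b = gene_b, table = tab,
                 divergent_tissues = div,
                 is_divergent = length(div) >= 1, alpha = alpha),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("divergence_result:", x$gene_a, "vs", x$gene_b, "-",
      if (x$is_divergent) "divergent in" else "no divergence;",
      if (x$is_divergent) paste(x$divergent_tissues, collapse = ", ") else
        paste0("alpha = ", x$alpha), "\n")
  invisible(x)
}
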