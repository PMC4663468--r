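test_that("normalization centers gene rows on the log scale", {
  m <- rbind(const = rep(7, 6), ramp = c(0, 1, 3, 0, 1, 3))
  norm <- normalize_expression(m)
  expect_true(all(abs(apply(norm, 1, median)) < 1e-9))
  expect_equal(unname(norm["const", ]), rep(0, 6))
  expect_equal(unname(norm["ramp", 1:3]), c(-1, 0, 1))
  expect_error(normalize_expression(rbind(a = c(-1, 2))), "negative")
  # the centering step is idempotent
  again <- normalize_expression(norm, log2_transform = FALSE)
  expect_equal(again, norm)
})

make_expr_fixture <- function(shift_tissue = NULL, shift = 0, seed = 1,
                              reps = 3, tissues = 4) {
  set.seed(seed)
  samples <- paste0("T", rep(seq_len(tissues), each = reps), "_",
                    rep(seq_len(reps), tissues))
  groups <- setNames(paste0("T", rep(seq_len(tissues), each = reps)),
                     samples)
  base <- rnorm(tissues, 3, 1)
  a <- rep(base, each = reps) + rnorm(tissues * reps, 0, 0.3)
  b <- rep(base, each = reps) + rnorm(tissues * reps, 0, 0.3)
  if (!is.null(shift_tissue))
    b[groups == shift_tissue] <- b[groups == shift_tissue] + shift
  m <- rbind(gA = a, gB = b)
  colnames(m) <- samples
  list(mat = m, groups = groups)
}

test_that("identical expression profiles are not divergent", {
  fx <- make_expr_fixture(seed = 2)
  m <- fx$mat; m["gB", ] <- m["gA", ]
  dv <- paralog_divergence_test("gA", "gB", m, fx$groups)
  expect_false(dv$is_divergent)
  expect_length(dv$divergent_tissues, 0)
})

test_that("a large planted shift is detected in the right tissue", {
  fx <- make_expr_fixture(shift_tissue = "T2", shift = 4, seed = 3)
  dv <- paralog_divergence_test("gA", "gB", fx$mat, fx$groups)
  expect_true(dv$is_divergent)
  expect_true("T2" %in% dv$divergent_tissues)
})

test_that("the test is symmetric and monotone in alpha", {
  fx <- make_expr_fixture(shift_tissue = "T3", shift = 2, seed = 4)
  d1 <- paralog_divergence_test("gA", "gB", fx$mat, fx$groups)
  d2 <- paralog_divergence_test("gB", "gA", fx$mat, fx$groups)
  expect_equal(d1$table$p_value, d2$table$p_value, tolerance = 1e-12)
  expect_setequal(d1$divergent_tissues, d2$divergent_tissues)
  strict <- paralog_divergence_test("gA", "gB", fx$mat, fx$groups,
                                    alpha = 0.001)
  expect_true(all(strict$divergent_tissues %in% d1$divergent_tissues))
})

test_that("tissues with fewer than two replicates are skipped with warning", {
  fx <- make_expr_fixture(seed = 5)
  keep <- c(colnames(fx$mat)[fx$groups != "T4"], "T4_1")
  m <- fx$mat[, keep]
  expect_warning(dv <- paralog_divergence_test("gA", "gB", m,
                                               fx$groups[keep]),
                 "T4")
  expect_false("T4" %in% dv$table$tissue)
  expect_error(paralog_divergence_test("gA", "missing", fx$mat, fx$groups),
               "missing")
})
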