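test_that("planted elements are recovered boundary-exact for all classes", {
  for (cls in c("LTR", "Helitron", "CACTA", "MULE", "hAT")) {
    for (s in 1:3) {
      w <- simulate_te_window(cls, seed = 40 + s)
      det <- detect_te_elements(w$seq, cls)
      expect_true(any(det$start == w$start & det$end == w$end),
                  label = paste(cls, "seed", 40 + s))
    }
  }
})

test_that("a Helitron without its terminal CTAG is not called", {
  w <- simulate_te_window("Helitron", seed = 50)
  chars <- strsplit(w$seq, "")[[1]]
  # ablate the 3' terminus (last four bases of the element)
  chars[(w$end - 3):w$end] <- c("A", "A", "A", "A")
  det <- detect_te_elements(paste(chars, collapse = ""), "Helitron")
  expect_false(any(det$start == w$start))
})

test_that("an LTR element without its TSD is not called", {
  set.seed(61)
  host <- famevol:::random_dna(30000, 0.4)
  el <- build_te_element("LTR", seed = 62)
  # insert without duplicating the target site
  seq <- paste0(substr(host, 1, 12000), el$seq, substr(host, 12001, 30000))
  det <- detect_te_elements(seq, "LTR")
  expect_equal(nrow(det), 0)
})

test_that("TE recall degrades as planted elements accumulate mutations", {
  recall_at <- function(rate) {
    hit <- 0
    for (s in 1:6) {
      w <- simulate_te_window("CACTA", mutation_rate = rate, seed = 70 + s)
      det <- detect_te_elements(w$seq, "CACTA")
      if (nrow(det) > 0 &&
          any(abs(det$start - w$start) <= 2 & abs(det$end - w$end) <= 2))
        hit <- hit + 1
    }
    hit / 6
  }
  r0 <- recall_at(0); r_hi <- recall_at(0.25)
  expect_equal(r0, 1)
  expect_lt(r_hi, r0)
})

test_that("short windows yield empty results, not errors", {
  expect_equal(nrow(detect_te_elements("ACGTACGT", "LTR")), 0)
  expect_error(detect_te_elements("ACGT", "unknown_class"), "unknown")
})
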