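# Structural transposable-element detectors. Each detector searches a
# nucleotide window (typically the 50-kb flanks around a candidate gene)
# for the class-defining termini, repeats and target-site duplications:
#   LTR retrotransposon: two direct repeats (TG...CA) flanked by a 4-6 bp TSD;
#   Helitron: TC 5' terminus, CTAG 3' terminus preceded by a hairpin
#     palindrome, inserted between host A and T;
#   CACTA: terminal inverted repeats beginning CACTA, 3-bp TSD;
#   MULE: long TIRs (>= 40 bp) with 9-10 bp TSD;
#   hAT: short TIRs with 8 bp TSD.

COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A")

te_default_params <- function(element_class) {
  switch(element_class,
    LTR = list(min_ltr = 100, max_ltr = 3000, min_spacing = 1000,
               max_spacing = 15000, min_identity = 0.8, tsd_range = 4:6,
               seed_k = 20),
    Helitron = list(motif_5p = "TCTCTACTA", min_len = 500, max_len = 20000,
                    min_stem = 6, max_loop = 4, min_stem_gc = 0.75,
                    pal_window = 30),
    CACTA = list(min_tir = 12, min_len = 200, max_len = 30000, tsd_len = 3),
    MULE = list(min_tir = 40, min_len = 200, max_len = 30000,
                tsd_range = 9:10, seed_k = 15),
    hAT = list(min_tir = 10, min_len = 100, max_len = 30000, tsd_len = 8,
               seed_k = 10),
    stop("unknown element class: ", element_class))
}

str_positions <- function(chars, pattern) {
  p <- strsplit(pattern, "")[[1]]
  n <- length(chars); k <- length(p)
  if (n < k) return(integer())
  ok <- chars[1:(n - k + 1)] == p[1]
  if (k > 1) for (t in 2:k) ok <- ok & chars[t:(n - k + t)] == p[t]
  which(ok)
}

#' Detect transposable elements in a sequence window by structure
#'
#' Runs the class-specific structural search described above. Detector
#' parameters (TIR lengths, spacing, identity, terminal motifs) are
#' config-exposed through `params`; defaults are documented in the methods
#' vignette. The Helitron detector requires, beyond the invariant TC/CTAG
#' termini, a 5'-terminal family consensus motif (default 9 bp beginning
#' TC) because the two-base terminus alone cannot localize the 5' boundary.
#'
#' @param window_seq nucleotide sequence (character or `DNAString`).
#' @param element_class one of `"LTR"`, `"Helitron"`, `"CACTA"`, `"MULE"`,
#'   `"hAT"`.
#' @param params named list overriding class defaults.
#' @return data.frame of annotations with `element_class`, 1-based `start`,
#'   `end` within the window, `tsd`, and class-specific columns; zero rows
#'   when nothing qualifies or the window is shorter than a minimal element.
#' @export
detect_te_elements <- function(window_seq, element_class, params = list()) {
  p <- utils::modifyList(te_default_params(element_class), params)
  seq <- toupper(as.character(window_seq))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  empty <- data.frame(element_class = character(), start = integer(),
                      end = integer(), tsd = character())
  if (n < 50) return(empty)
  out <- switch(element_class,
                LTR = detect_ltr(chars, p),
                Helitron = detect_helitron(chars, p),
                CACTA = detect_cacta(chars, p),
                MULE = detect_tir_element(chars, p, "MULE", p$tsd_range),
                hAT = detect_tir_element(chars, p, "hAT", p$tsd_len))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[!duplicated(paste(out$start, out$end)), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

check_tsd <- function(chars, left_start, right_end, lens) {
  n <- length(chars)
  for (t in sort(lens, decreasing = TRUE)) {
    if (left_start - t < 1 || right_end + t > n) next
    a <- chars[(left_start - t):(left_start - 1)]
    b <- chars[(right_end + 1):(right_end + t)]
    if (all(a == b)) return(paste(a, collapse = ""))
  }
  NULL
}

detect_ltr <- function(chars, p) {
  n <- length(chars); k <- p$seed_k
  if (n < 2 * p$min_ltr + p$min_spacing) return(NULL)
  seqstr <- paste(chars, collapse = "")
  kmers <- substring(seqstr, 1:(n - k + 1), k:n)
  grp <- split(seq_len(n - k + 1), kmers)
  grp <- grp[lengths(grp) >= 2]
  offsets <- integer()
  for (g in grp) {
    if (length(g) > 8) next  # low-complexity repeat, skip
    cmb <- utils::combn(g, 2)
    d <- cmb[2, ] - cmb[1, ]
    offsets <- c(offsets, d)
  }
  offsets <- sort(unique(offsets))
  offsets <- offsets[offsets >= p$min_ltr + p$min_spacing &
                       offsets <= p$max_ltr + p$max_spacing]
  rows <- list()
  for (d in offsets) {
    b <- chars[1:(n - d)] == chars[(1 + d):n]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values & r$lengths >= k)
    if (length(runs) == 0) next
    # merge nearby true runs (tolerating point mutations)
    spans <- cbind(starts[runs], ends[runs])
    merged <- list(); cur <- spans[1, ]
    if (nrow(spans) > 1) for (i in 2:nrow(spans)) {
      if (spans[i, 1] - cur[2] <= 25) cur[2] <- spans[i, 2]
      else { merged[[length(merged) + 1L]] <- cur; cur <- spans[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    for (sp in merged) {
      s5 <- sp[1]; e5 <- sp[2]
      len <- e5 - s5 + 1
      if (len < p$min_ltr || len > p$max_ltr) next
      ident <- mean(b[s5:e5])
      if (ident < p$min_identity) next
      spacing <- d - len
      if (spacing < p$min_spacing || spacing > p$max_spacing) next
      # enforce TG...CA termini on both repeats, trimming at most 3 bp
      s5a <- s5; e5a <- e5; ok <- FALSE
      for (ts in 0:3) {
        if (chars[s5 + ts] == "T" && chars[s5 + ts + 1] == "G" &&
            chars[s5 + d + ts] == "T" && chars[s5 + d + ts + 1] == "G") {
          s5a <- s5 + ts; ok <- TRUE; break
        }
      }
      if (!ok) next
      ok <- FALSE
      for (te in 0:3) {
        if (chars[e5 - te - 1] == "C" && chars[e5 - te] == "A" &&
            chars[e5 + d - te - 1] == "C" && chars[e5 + d - te] == "A") {
          e5a <- e5 - te; ok <- TRUE; break
        }
      }
      if (!ok) next
      s3 <- s5a + d; e3 <- e5a + d
      tsd <- check_tsd(chars, s5a, e3, p$tsd_range)
      if (is.null(tsd)) next
      rows[[length(rows) + 1L]] <- data.frame(
        element_class = "LTR", start = s5a, end = e3, tsd = tsd,
        ltr5_start = s5a, ltr5_end = e5a, ltr3_start = s3, ltr3_end = e3,
        ltr_identity = mean(b[s5a:e5a]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Maximal hairpin (inverted repeat with a short loop) whose right arm ends
# within [lo, hi]. Parametrized by the loop: for loop start c+1 and loop
# length l, pairing t matches chars[c - t + 1] against the complement of
# chars[c + l + t]; the stem is the maximal t.
find_hairpin <- function(chars, lo, hi, min_stem, max_loop, min_gc = 0) {
  n <- length(chars)
  lo <- max(lo, 2); hi <- min(hi, n)
  if (hi < lo) return(NULL)
  for (c in seq(hi, lo)) {
    for (loop in 0:max_loop) {
      a <- 0L
      while (c - a >= 1 && c + loop + a + 1 <= n &&
             chars[c - a] == COMP_MAP[[chars[c + loop + a + 1]]]) {
        a <- a + 1L
      }
      if (a >= min_stem) {
        e <- c + loop + a
        stem_gc <- mean(chars[(c - a + 1):c] %in% c("G", "C"))
        if (e >= lo && e <= hi && stem_gc >= min_gc)
          return(list(start = c - a + 1, end = e, stem = a, loop = loop))
      }
    }
  }
  NULL
}

detect_helitron <- function(chars, p) {
  n <- length(chars)
  starts <- str_positions(chars, p$motif_5p)
  starts <- starts[starts > 1 & chars[pmax(starts - 1, 1)] == "A"]
  if (length(starts) == 0) return(NULL)
  ends4 <- str_positions(chars, "CTAG")
  rows <- list()
  for (e4 in ends4) {
    e <- e4 + 3L                       # last base of CTAG
    if (e + 1 > n || chars[e + 1] != "T") next
    hp <- find_hairpin(chars, e4 - p$pal_window, e4 - 1, p$min_stem,
                       p$max_loop, p$min_stem_gc %||% 0)
    if (is.null(hp)) next
    cand <- starts[starts >= e - p$max_len + 1 & starts <= e - p$min_len + 1]
    if (length(cand) == 0) next
    s <- max(cand)                     # nearest valid 5' terminus
    rows[[length(rows) + 1L]] <- data.frame(
      element_class = "Helitron", start = s, end = e, tsd = "",
      palindrome_start = hp$start, palindrome_end = hp$end,
      stem_len = hp$stem, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

detect_cacta <- function(chars, p) {
  n <- length(chars)
  lefts <- str_positions(chars, "CACTA")
  rights <- str_positions(chars, "TAGTG")    # revcomp of CACTA
  if (length(lefts) == 0 || length(rights) == 0) return(NULL)
  rows <- list()
  for (s in lefts) {
    re <- rights + 4L                        # last base of right terminus
    re <- re[re - s + 1 >= p$min_len & re - s + 1 <= p$max_len]
    for (e in re) {
      t <- 0L
      while (s + t < e - t &&
             chars[s + t] == COMP_MAP[[chars[e - t]]]) t <- t + 1L
      if (t < p$min_tir) next
      tsd <- check_tsd(chars, s, e, p$tsd_len)
      if (is.null(tsd)) next
      rows[[length(rows) + 1L]] <- data.frame(
        element_class = "CACTA", start = s, end = e, tsd = tsd,
        tir_len = t, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

detect_tir_element <- function(chars, p, class_name, tsd_lens) {
  n <- length(chars); k <- p$seed_k
  if (n < 2 * p$min_tir + 10) return(NULL)
  seqstr <- paste(chars, collapse = "")
  kmers <- substring(seqstr, 1:(n - k + 1), k:n)
  rc <- vapply(kmers, function(x)
    paste(rev(COMP_MAP[strsplit(x, "")[[1]]]), collapse = ""), character(1))
  hit <- match(rc, kmers)
  rows <- list()
  seen <- character()
  for (i in which(!is.na(hit))) {
    j <- hit[i]                 # kmer at j is revcomp of kmer at i
    if (j <= i) next
    left <- i; right <- j + k - 1L
    if (right - left + 1 > p$max_len) next
    # extend outward
    while (left > 1 && right < n &&
           chars[left - 1] == COMP_MAP[[chars[right + 1]]]) {
      left <- left - 1L; right <- right + 1L
    }
    # arm length: extend inward from the seed
    arm <- i - left + k
    li <- i + k; ri <- j - 1L
    while (li < ri && chars[li] == COMP_MAP[[chars[ri]]]) {
      arm <- arm + 1L; li <- li + 1L; ri <- ri - 1L
    }
    if (arm < p$min_tir) next
    if (right - left + 1 < p$min_len) next
    key <- paste(left, right)
    if (key %in% seen) next
    seen <- c(seen, key)
    # the outward extension can overrun the true termini by chance
    # complementarity between the flanks; trim back until the TSD matches
    for (trim in 0:4) {
      if (arm - trim < p$min_tir) break
      tsd <- check_tsd(chars, left + trim, right - trim, tsd_lens)
      if (!is.null(tsd)) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_class = class_name, start = left + trim,
          end = right - trim, tsd = tsd, tir_len = arm - trim,
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
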