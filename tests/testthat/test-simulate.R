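test_that("with all rates zero the family stays single-copy everywhere", {
  cfg <- sim_config(birth_rates = c(tandem = 0, segmental = 0, TE = 0,
                                    retro = 0))
  tr <- simulate_family_history(cfg, seed = 1)
  expect_equal(nrow(tr$extant), 4)
  expect_true(all(tr$mrca_counts == 1))
  expect_equal(nrow(tr$events), 0)
})

test_that("the history is deterministic given the seed", {
  cfg <- sim_config()
  t1 <- simulate_family_history(cfg, seed = 9)
  t2 <- simulate_family_history(cfg, seed = 9)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$extant, t2$extant)
  t3 <- simulate_family_history(cfg, seed = 10)
  expect_false(identical(t1$nodes, t3$nodes))
})

test_that("birth events on one branch follow the pure-birth expectation", {
  # E[events] = exp(b*T) - 1 = 5 for b*T = log(6)
  b <- log(6) / 2
  cfg <- sim_config(species_tree = "(A:2,B:0.0001)AB;",
                    birth_rates = c(tandem = b, segmental = 0, TE = 0,
                                    retro = 0))
  counts <- vapply(1:300, function(s) {
    tr <- simulate_family_history(cfg, seed = s)
    sum(tr$events$species_edge == "A")
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 5), 3 * se)
})

test_that("zero-length branches leave sequences unchanged", {
  cfg <- sim_config(species_tree = "(A:0.0,B:0.5)AB;",
                    birth_rates = c(tandem = 0, segmental = 0, TE = 0,
                                    retro = 0))
  tr <- simulate_family_history(cfg, seed = 2)
  seqs <- evolve_codon_sequences(tr, cfg, seed = 3)
  # A sits at zero distance from the root: its sequence is the root state;
  # re-simulating with the same seed reproduces it exactly
  seqs2 <- evolve_codon_sequences(tr, cfg, seed = 3)
  expect_identical(seqs$cds, seqs2$cds)
  expect_equal(nchar(seqs$cds[[grep("^A", names(seqs$cds), value = TRUE)]]),
               3 * cfg$gene_codons)
})

test_that("positive-class sites diverge faster than purifying ones", {
  tree <- ape::read.tree(text = "(x:0.3,y:0.3);")
  aa_diff <- function(w, s) {
    aln <- simulate_codon_alignment(tree, rep(w, 150), seed = s)
    p1 <- famevol:::split_codons(aln[[1]])
    p2 <- famevol:::split_codons(aln[[2]])
    mean(Biostrings::GENETIC_CODE[p1] != Biostrings::GENETIC_CODE[p2])
  }
  lo <- vapply(1:8, function(s) aa_diff(0.1, s), numeric(1))
  hi <- vapply(1:8, function(s) aa_diff(2.0, 100 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("TE fragment copies carry the configured parent region", {
  expect_equal(famevol:::fragment_codon_range(2, 100), 60:100)
  expect_equal(famevol:::fragment_codon_range(3, 100), 1:40)
  expect_equal(famevol:::fragment_codon_range(4, 100), 20:70)
})

test_that("emitted datasets are complete and byte-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config()
  simulate_dataset(cfg, seed = 6, out_dir = d1, force = TRUE)
  simulate_dataset(cfg, seed = 6, out_dir = d2, force = TRUE)
  files <- c("genome.fasta", "annotation.gff3", "cds.fasta",
             "proteins.fasta", "expression.tsv", "species_tree.nwk",
             "truth.json", "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # truth gene count equals annotated family gene count in the GFF3
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  gff <- ape::read.gff(file.path(d1, "annotation.gff3"), GFF3 = TRUE)
  gene_ids <- sub(".*ID=([^;]+).*", "\\1",
                  gff$attributes[gff$type == "gene"])
  fam_in_gff <- gene_ids[!grepl("FIL", gene_ids)]
  expect_setequal(truth$extant$gene_id, fam_in_gff)
  # refusing to clobber an existing dataset
  expect_error(simulate_dataset(cfg, seed = 6, out_dir = d1), "force")
})

test_that("planted mechanism evidence is recoverable from the layout", {
  mg <- simulate_mechanism_genome(n_tandem_pairs = 3, n_segmental = 2,
                                  n_te = 2, n_retro = 2, n_ancestral = 2,
                                  seed = 5)
  truth <- mg$truth
  fam <- truth$gene_id
  # tandem
  arrays <- detect_tandem_arrays(fam, mg$annotation)
  detected_t <- unlist(lapply(arrays, `[[`, "member_ids"))
  expect_setequal(intersect(detected_t, fam),
                  truth$gene_id[truth$mechanism == "tandem"])
  # retro
  retro <- detect_retrogenes(fam, mg$annotation)
  expect_setequal(retro$retro_id,
                  truth$gene_id[truth$mechanism == "retro"])
  # TE structural evidence at the planted coordinates
  for (k in seq_len(nrow(mg$te_truth))) {
    tt <- mg$te_truth[k, ]
    win <- substr(mg$genome[[tt$chromosome]], tt$start - 2000,
                  tt$end + 2000)
    det <- detect_te_elements(win, tt$element_class)
    expect_true(nrow(det) > 0, label = paste("TE", tt$gene_id))
  }
})
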