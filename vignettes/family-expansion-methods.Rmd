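---
title: "Methods: gene-family expansion, selection and expression divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family expansion, selection and expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The analysis chain

famevol studies protein-domain-defined gene families — its defaults are
tuned to the four sucrose-metabolism enzyme families (SuSy, SPS, SPP,
UDPGP), identified purely by Pfam domain content (PF00862;
PF00534 + PF05116; PF05116 alone; PF01704) — through five stages: family
census, expansion-mechanism classification, reconciliation-based history,
selection analysis, and paralog expression divergence. Each stage is a
set of exported functions; `run_pipeline()` orchestrates them.

## Family census

**Profile model.** Each domain is a position-specific scoring matrix
(PSSM) with affine gaps, not a full profile HMM: consensus columns are
seed-alignment columns with under 50% gaps; scores are log-odds in
half-bit units, `2 log2(p_a / bg_a)`, with background-proportional
pseudocounts (total mass `20 × 0.5` per column) over Robinson–Robinson
background frequencies. The census decision rules — search cutoff
E ≤ 1.0, domain confirmation E ≤ 0.01, the SPS/SPP domain-combination
partition — carry the scientific content; users who want a production
HMM engine can feed `read_domtbl()` output into `assign_families()`
unchanged.

**E-values.** Significance is empirical: each protein is shuffled (200
decoys by default), a Gumbel distribution is fitted to the decoy scores
by the method of moments, and E = (Gumbel tail probability) × (number of
proteins scanned). A two-stage search keeps this affordable: a 32-decoy
pilot null screens out sequences whose score is nowhere near the
reporting threshold (pilot E > 50 × cutoff), and only candidates get the
full null — the same filter-pipeline logic production scanners use. The
test suite verifies the calibration property that a scan of random
proteins yields on the order of one E ≤ 1 hit.

**Partial members.** Genes whose best hit covers less than 70% of the
profile *and* that lack expression evidence are retained in the census
table but flagged `partial_excluded` and dropped from phylogenetic and
codon analyses. The 0.7 coverage default quantifies "partial domain";
expression evidence is an explicit gene-id allow-list, since no
particular evidence type is privileged.

## Expansion mechanisms

**Tandem arrays.** Within-family pairs qualify when (1) the local
alignment (Smith–Waterman, BLOSUM62, gap open 11 / extend 1) covers at
least 30% of the *shorter* protein — a "query" coverage rule is ambiguous
for a symmetric pair, so the conservative reading is used; (2) identity is at
least 70%; (3) at most 10 genes intervene; and (4) the genomic span from
the upstream gene's start to the downstream gene's end is within the
genome-class window — 100 kb for compact genomes (algae,
*Arabidopsis*-sized), 350 kb otherwise. Qualifying pairs merge into
arrays by single linkage. `tandem_pair_decision()` exposes the bare
four-way decision so the boundaries are directly testable.

**Segmental blocks.** Collinear anchor pairs (protein alignments at
E ≤ 0.01 between 50-kb windows around family genes) are chained by
dynamic programming over chromosome ranks, DAGchainer-style: chain score
is the anchor-score sum minus a gap penalty of 1.0 per skipped rank unit,
transitions with rank gaps above 10 are disallowed, both orientations are
tried, and blocks need at least 5 anchor pairs. "Inside a block" for a
family gene means being an anchor or lying in the convex hull of the
block's anchors extended by the 50-kb flank. The chaining DP is proven
equal to exhaustive best-chain search on all instances with ≤ 8 anchors.
Whole-genome-duplication attribution is deliberately left to the user:
positional evidence alone cannot separate WGD remnants from segmental
blocks.

**TE structural detectors.** Class signatures, searched in 50-kb flanks:

* *LTR*: two direct repeats of 100–3000 bp at ≥ 80% identity, 1–15 kb
  apart, each starting TG and ending CA, flanked by an identical 4–6 bp
  target-site duplication (TSD). Detection seeds on exact 20-mer matches,
  merges match runs (tolerating point mutations), trims termini to the
  TG…CA motifs, and requires the TSD.
* *Helitron*: 5′ terminus beginning TC, 3′ terminus CTAG preceded within
  30 bp by a terminal hairpin, inserted between host A and T. Two
  detector choices deserve note. First, a two-base 5′ terminus cannot
  localize a boundary (an A + TC occurs every ~128 bp of random DNA), so
  the detector takes a 5′-terminal family-consensus motif parameter
  (default 9 bp beginning TC), exactly as production Helitron finders
  use learned terminal consensi; the simulator plants the same family
  consensus. Second, the hairpin stem must be GC-rich (≥ 0.75 over a
  ≥ 6 bp stem, loop ≤ 4), as real Helitron hairpins are; without this the
  false-positive rate on random 50-kb windows is around 0.1 per window
  instead of well under 0.05.
* *CACTA*: terminal inverted repeats whose outer ends begin CACTA, with a
  3-bp TSD. The default minimum TIR length is 12 bp: an a-priori
  false-positive analysis on random 50-kb windows puts the expected FP
  count at ~0.04 per window for 10-bp TIRs (uncomfortably near the 0.05
  design bound) and ~2×10⁻³ for 12 bp. Config-exposed.
* *MULE* (TIR ≥ 40 bp, TSD 9–10 bp) and *hAT* (TIR ≥ 10 bp, TSD 8 bp),
  seeded by reverse-complement k-mer matching with outward/inward
  extension; boundary overruns caused by chance complementarity between
  the flanking TSD copies are trimmed back until the TSD matches.

**Fragment types.** A TE-carried copy is typed by the region of the
parent protein its alignment spans: type 1 (whole) touches both termini,
type 2 only the 3′ terminus, type 3 only the 5′ terminus, type 4
neither; "touching" means reaching into the first/last 10% of the
parent. The 10% threshold quantifies the published examples, which give
cases rather than a number.

**Retrogenes.** Single-exon family members whose best multi-exon family
paralog passes identity ≥ 50% and coverage ≥ 0.7 (the conventional
retrogene criteria; config-exposed), with `introns_lost` = parent exon
count − 1.

Mechanism labels are multi-valued with no precedence: a gene can be
TE-carried *and* sit in a segmentally duplicated block, and real
families show exactly that.

## Family history

Gene trees are neighbor joining (canonical Saitou–Nei, via ape) on
Poisson-corrected distances `d = −ln(1 − p)` from domain protein
alignments, with column-bootstrap support. NJ + bootstrap replaces
heavier parsimony/Bayesian machinery deliberately: only the topology
feeds the downstream counting, and the simulated-truth tests validate
the chain end to end. Rooting minimizes the implied duplication count
over all edges (ties go to the midpoint root). Reconciliation is LCA
mapping: each gene-tree node maps to the lowest species-tree node
containing its descendant species; a node is a duplication iff its
children's species sets intersect.

The ancestral (MRCA) copy count at a species divergence counts lineages
present at that instant: speciation nodes mapped exactly to the node,
plus gene-tree edges whose parent maps strictly above and child strictly
below it. Duplication nodes mapping to the node contribute through their
child speciations. No losses are inferred beyond spanning edges, so the
count is a lower bound when lineages were lost — matching the
caveat that pseudogene exclusion biases ancestral counts downward.

## Selection

**Pair filters.** Protein alignments are back-translated onto their CDS
(`backtranslate()`, with hard errors on any translation mismatch); a pair
enters Ka/Ks estimation only if the ungapped overlap exceeds 150 bp and
nucleotide identity over the overlap is at least 70%.

**NG86.** Synonymous site counts are fractional per codon position with
stop-leading changes excluded from the denominator (so S + N = 3 × codons
exactly); differences between codons are averaged over all orderings of
the differing positions, excluding pathways through stop codons (with
renormalization; if every pathway hits a stop, all are kept); proportions
are Jukes–Cantor corrected, with `p ≥ 0.75` a hard "saturated" error, and
Ks = 0 yields an undefined ratio rather than an error. Codon columns
containing a gap or an ambiguous base in either sequence are dropped
pairwise; an observed in-frame stop is a data error. The implementation
is held exactly equal to an explicit pathway-enumeration oracle on
thousands of random pairs.

**YN00-compatible mode.** Site counts and pathway steps are weighted by a
transition/transversion ratio κ estimated from third-position
differences (K80 form) and position-specific target-base frequencies
(F3×4). It is a counting-level approximation validated against NG86 on
simulated pairs (|Δ(Ka/Ks)| ≤ 0.2), not a reimplementation of the
iterative yn00 estimator.

**Sitewise scan.** A simplified Muse–Gaut-style codon model over the 61
sense codons with uniform codon frequencies: relative rate κ for
transitions and ω for nonsynonymous changes, and the rate matrix
normalized by the *neutral* (ω = 1) rate constant, so branch lengths are
substitutions per site at ω = 1 and positively selected sites evolve
proportionally faster — the property the test statistic draws most of
its power from. Stage one estimates κ, a branch-scale factor and a
single global ω by maximum likelihood (Felsenstein pruning, eigendecomposition
of the symmetric rate matrix). Stage two maximizes each site's likelihood
over ω ∈ [0, 50] — a shared log-spaced ω grid evaluated for all sites at
once (eigendecompositions shared), then golden-section refinement to
|Δω| ≤ 10⁻⁴ in the bracketing cell with decomposition memoization — and
tests against ω = 1 by 2ΔlnL on χ²₁. No boundary ½-mixture correction is
applied, which is conservative for the positive tail. Classification:
positive iff ω̂ > 1 and p < α; purifying iff ω̂ < 1 and p < α. All-gap
sites are reported untested. The pruning likelihood is held to within
10⁻⁸ of a direct 61²-state summation on three-taxon cases.

## Expression divergence

Expression values are `log2(x + 1)`-transformed and median-centered per
gene (the centering step is idempotent; the log transform is a flag
because re-logging a centered matrix is undefined for its negative
entries). For each paralog pair, each tissue with ≥ 2 replicates per gene
gets a two-sample t-test; the pair is divergent when any tissue has
p < 0.05. No multiple-testing correction is applied across tissues by
default — that is the procedure being reproduced — with
Benjamini–Hochberg behind a flag. The package default is the Welch
(unequal-variance) form for robustness; the classical pooled Student form
is available via `var_equal = TRUE` and is what the calibration checks
exercise, because at three replicates the pooled test is exact under the
replicate model (simulated size 0.050, power 0.993 for a 5-SD shift)
while Welch is conservative (size ≈ 0.041, power ≈ 0.970).

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws a gene-family history along a dated species
tree (Gillespie birth/loss per lineage; the default four-species tree has
tip branches of 0.30–0.35 and internal branches of 0.15–0.20 expected
substitutions per codon site), assigns each birth a mechanism (default
rates per branch-length unit: tandem 0.8, segmental 0.4, TE 0.4, retro
0.25; loss 0), draws TE classes uniformly over LTR/Helitron/CACTA and
carried-fragment types at the observed 40/17.1/28.6/14.3 percentages,
evolves codon sequences under per-site ω classes (defaults 0.1/0.5/1.0
at proportions 0.6/0.35/0.05 — purifying-dominated, as domain regions
are; κ = 2), and lays out each species' genome with the mechanism's
positional signature: tandem copies adjacent to their source, segmental
copies inside a duplicated run of ≥ 5 neighboring genes, TE copies
wrapped in a structural element, retro copies intron-less. Intergenic
DNA is i.i.d. at 40% GC — detectors need decoys, not realistic repeat
landscapes. Expression matrices plant additive shifts (default 2 units
on the log2 scale, noise SD 0.5, 16 tissues × 3 replicates, divergence
probability 0.5) for recent paralog pairs.

Deliberate simplifications, and what they mean for the tests: no indels
within coding sequence (alignments are known by construction, so
alignment error is untested); losses delete genes without pseudogene
remnants; all simulated genes sit on the plus strand (minus-strand
handling is exercised by the I/O unit fixtures instead); within-species
placement of genes born before the last speciation is approximate —
tandem-derived genes cluster together rather than next to their exact
parent copy, and unrelated family placements are separated by at least
11 filler genes so that sequence similarity alone can never satisfy the
tandem proximity criterion. Passing tests therefore demonstrate that the
decision rules and estimators recover planted structure under their own
assumptions, not that they are robust to misannotation, alignment error
or repeat-rich genomic context.

Study sizes used by the checks (chosen to characterize each method at
desk scale): the NG86 oracle comparison runs 1000 random 60-codon pairs;
chaining is compared with exhaustive search on 500 instances of ≤ 8
anchors; reconciliation truth uses 100 loss-free histories on a
four-species tree with 0.4/0.25 branch lengths, single ω class 0.6 and
300-codon genes — branch lengths long enough to be informative and short
enough that Poisson distances stay far from saturation; TE calibration
uses 100 random 50-kb decoy windows per class; the sitewise calibration
uses 200 replicates of a 4-taxon alignment (branches 0.3/0.24, 30 codons,
one ω = 5 site), conditions fixed after a pilot power analysis; the
expression calibration uses 1000 null pairs across 16 tissues and 500
power replicates.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout (GFF3 convention); any
half-open arithmetic is confined to private helpers. All randomized
operations take explicit integer seeds and derive per-item streams from
them; no global random state is relied on. Negative NJ branch lengths
are clamped to zero. Distance computations error on pairs sharing fewer
than 30 non-gap columns and on saturated pairs. Genes with ambiguous
nucleotides are retained for the census but their affected codon columns
are dropped pairwise from Ka/Ks. Ties — equidistant reciprocal best
partners, equal-score rootings — break deterministically by label order
and are logged as warnings.

## Known limitations

The PSSM census has no forward-algorithm E-values and models no
multi-domain architectures beyond the four target domains. The sitewise
scan shares κ and branch lengths across sites but ignores among-site
rate variation beyond ω itself, and its χ²₁ reference is conservative at
the ω = 1 boundary. The YN00-compatible mode is a weighted-counting
approximation. Solo-LTR elements, nested TEs, and TE superfamilies
beyond the five named classes are out of scope, as is distinguishing
whole-genome duplication from segmental blocks.
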