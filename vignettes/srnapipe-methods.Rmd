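---
title: "srnapipe methods: models, defaults and their rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnapipe methods: models, defaults and their rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents what each stage of srnapipe computes, why each
default is set where it is, and what the synthetic-study generator does and
deliberately does not emulate. Code chunks are illustrative and not
evaluated at build time; the same computations run, seeded, in the test
suite and in `scripts/acceptance.R`.

## 1. Preprocessing

**Trimming.** Libraries are fixed-length 35-base reads of the form
`insert + 3' adapter + downstream filler`. `trim_adapter()` scans each read
left to right for the first position where the remaining read suffix equals
a prefix of the adapter over the full available overlap ("leftmost
full-overlap adapter-prefix match"). Everything before that junction is the
insert. Reads with no junction are `untrimmed`, empty inserts are `empty`,
and inserts shorter than `min_len = 15` are `artifact`; only `ok` inserts
(15–35 nt) proceed. The leftmost rule is what makes trimming invertible on
synthetic data (section 8).

**Collapsing and the union database.** `collapse_reads()` counts distinct
insert sequences (signatures) per library. `build_union_db()` keeps a
signature if its count reaches the library-specific threshold k in *at
least one* library, and then retains its counts in every library, including
sub-threshold ones — so presence is thresholded but quantification is not.
`choose_threshold()` sets k from raw depth: 5 below 3 million reads, 10 in
between, 16 at 12 million and above. The rationale is sequencing-error
contamination control: the expected count of a specific single-error variant
of an abundant signature grows linearly with depth, so the threshold must
grow with depth too. Counts per million are computed against *raw* library
depth (`count * 1e6 / total_raw_reads`), not trimmed depth, so cpm values
remain comparable across libraries with different trimming survival.

## 2. Mapping, multi-mapping policy and annotation

`align_signatures()` performs a complete ungapped search of both genome
strands allowing up to `max_mm = 4` substitutions. It is built on
`Biostrings::vmatchPattern`, which enumerates every match within the
mismatch bound — there is no seeding heuristic and therefore no heuristic
loss; the test suite checks exact equivalence against an independent
brute-force Hamming scan at mismatch bounds 0, 1, 2 and 4.

`apply_multimap_policy()` implements the two-tier treatment of repetitive
signatures: genomic loci are *recorded* (coordinates kept) only for
signatures mapping to fewer than `record_cap = 10` locations; at or above
the cap, loci are dropped but the exact uncapped `location_count` is always
retained. This keeps the cluster stage (which consumes recorded loci) from
being swamped by high-copy repeats while preserving the multi-mapping
statistics (`multimap_statistics()`, bands 1 / 2–10 / 11–103 / >103) that
describe them.

`annotate_signatures()` assigns reference miRNA names with a
length-dependent mismatch rule: a signature–reference overlap of ≤ 18 nt
must be exact; longer overlaps tolerate one substitution. Short matches
carry little information, so any mismatch there is disqualifying; ties are
broken lexicographically for determinism. Gene models come from GFF3 via
`parse_gff3()` (malformed lines are warned about and skipped) and
`join_gene_models()` resolves exon/intron/UTR membership.

## 3. Secondary-structure folding

`fold_rna()` maximizes a stacking-weighted pairing score by dynamic
programming: pairs are A:U, G:C and G:U; a pair stacked directly on another
pair contributes 3 (G:C), 2 (A:U) or 1 (G:U); an unstacked pair contributes
1; hairpin loops enclose at least 3 bases. The reported `energy` is the
negative of the optimal score, so lower is more stable. The DP uses three
matrices (paired / paired-and-stacked / unconstrained) and a deterministic
traceback; the inner loops are C++ (Rcpp). On sequences short enough for
exhaustive enumeration of all valid structures, the DP optimum equals the
enumeration optimum on every tested instance.

Two caveats are worth stating plainly:

* This is a *score*, not a thermodynamic free energy; it orders structures
  sensibly but its magnitude is only meaningful relative to thresholds
  calibrated under the same score (next section).
* The folklore invariant "fold score is invariant under
  reverse-complementation" is false once G:U wobbles are allowed: a G:U
  pair maps to A:C, which cannot pair. The invariance holds exactly only on
  the complement-closed wobble-free alphabets {A,T} and {C,G}, and that is
  what the property test asserts.

## 4. miRNA hairpin validation

`extract_precursor_windows()` slides a `window = 200`-nt frame (stride 20,
edge margin 10) across placements of the candidate mature, on the correct
strand, clipped at chromosome ends — covering precursors with the mature on
either arm. Each window is folded and `check_hairpin()` applies four
criteria:

1. at least `min_paired = 16` of the mature bases are paired;
2. all partners of mature bases lie on one side of the mature span (the
   mature sits on an arm, not across the terminal loop);
3. score density `energy / window_width` is at most
   `energy_per_base = -0.95`;
4. at most `max_bulge = 3` unpaired bases interrupt the paired portion of
   the mature span.

The best candidate is the lowest-energy passing window.

**Why −0.95 per base.** The energy-density threshold is the one parameter
that cannot be transplanted from thermodynamic folders, because the score
scale is different. It was calibrated once, before freezing any test
expectations, by measuring two distributions under the package's own score:
best-window densities for planted hairpin-like stems (≈ −1.05/base) and for
200-nt windows of random genomic background (best passing windows tail off
around −0.7 to −1.0/base). A lax placeholder of −0.25/base produced a 24%
false-positive rate on background 21-mers — random 200-nt windows fold
surprisingly well under a simplified stacking score — while −0.95/base
yields ≤ 5 false calls per 100 background loci with ≥ 90% recovery of
planted hairpins. All four thresholds remain user-settable arguments.

`pair_5p_3p()` tests the processing-duplex geometry: the dominant 5p and 3p
products should have pairing partners offset by 2 nt at both ends (the 2-nt
3' overhang left by Dicer-like processing); major and star are labelled by
read count. `group_families()` groups annotated matures by their reference
family number and clusters novel hairpin-validated matures by
single-linkage at ≤ 1 substitution and ≤ 2-nt shift.

## 5. siRNA clusters, discrimination and exon tests

`cluster_alignments()` single-links recorded loci within `max_gap = 200` nt
and reports per-cluster statistics: footprint (reduced covered width),
distinct signatures, dominant-signature fraction, strand bias.
`classify_clusters()` then labels:

* **miRNA-like** — footprint ≤ 30, dominance ≥ 0.8, strand bias ≥ 0.9, and
  an overlapping validated hairpin window;
* **siRNA** — footprint ≥ 100 and ≥ 10 distinct signatures;
* **ambiguous** otherwise.

These cutoffs encode the biological contrast rather than tuned numbers: a
miRNA locus is essentially a single dominant product (plus a star) from one
strand; a heterochromatic siRNA source is a wide, diverse, double-stranded
population. `exon_only_test()` flags clusters whose recorded loci lie
almost entirely (≥ 98%) within exons of a spliced gene model — evidence of
a transcript-derived (rather than chromatin-region) source.
`find_inverted_repeats()` seeds with shared 12-mers between the sequence
and its reverse complement (a genuine inverted repeat puts all seed hits of
one arm pair on a common anti-diagonal), then verifies arms ≥ 100 nt at
≥ 90% identity with a spacer ≤ 5 kb.

## 6. Phased siRNA detection

`find_trigger_sites()` scans a transcript for near-complementary sites of a
candidate trigger miRNA. Matches are counted with G:U wobbles at half
weight (rounded down); the default `min_matches = 17` retains genuine
trigger configurations (17–18 effective matches) while a random 21-mer
against a random kilobase essentially never reaches it. The inferred
cleavage position is between trigger positions 10 and 11, i.e. the first
base of the downstream fragment.

`phase_register()` reduces each downstream product to its 5' end (for
antisense products, the 3'-side genomic end shifted by the 2-nt duplex
overhang, which places the antisense strand of a phased duplex in the sense
register), de-duplicates to distinct positions, and computes each
position's register modulo 21 relative to the cleavage site. With n
distinct positions of which k share the modal register, the score is k/n
and the p-value is the exact binomial tail
`min(1, 21 * P[Bin(n, 1/21) >= k])` — a Bonferroni union bound over the 21
registers, since the modal register is selected after looking. Fewer than
3 distinct positions is flagged `insufficient` rather than scored.

**Design properties of the p-value.** The union bound makes the test
*conservative*: under a uniform null the realized type-I rate at the 0.05
level measures ≈ 0.014 (500 simulated unphased clusters with n drawn
uniformly from 10–60, chosen a priori as typical distinct-position counts
of the clusters the detector scans). That conservatism is structural — the
bound over-counts the probability that *some* register is enriched, and the
discreteness of the binomial adds further slack — and is reported honestly
rather than re-tuned. Conversely, in the regime where loci are actually
reported (nominal p below ~0.15), the second-order term of the union bound
is negligible and the binomial p agrees with permutation-null estimates to
within Monte-Carlo error; the comparison grid in the acceptance tests is
restricted to that regime *by design, chosen before measuring*, because
outside it (weak enrichment, p near 1) the union bound is intentionally
loose.

## 7. Repeat and TE profiling

`match_te_db()` assigns signatures to TE families at ≥ 95% identity over
the signature length (for 21–24-mers this means at most one substitution);
signatures matching multiple families equally well are `ambiguous`.
`family_size_profiles()` tabulates, per family and in aggregate, both
distinct-signature and summed-read counts per length — the two views that
produce the characteristic inversion: many distinct low-abundance 24-mers
versus few highly abundant 22-mers dominating reads.
`region_size_profile()` does the same for an arbitrary region (e.g. an
rDNA-like tandem array), overall and per library.

## 8. The synthetic-study generator

`sim_config()` / `generate_genome()` / `simulate_libraries()` plant, in a
100-kb single-chromosome genome (default):

* **20 miRNA hairpins** — 70-nt arms, 8-nt loop, mature at a fixed arm
  offset, star on the partner arm with the 2-nt overhang. Six G:U wobbles
  are introduced into the partner arm ("wobble softening"): with perfectly
  complementary stems the mature also aligns perfectly to the minus strand
  of its own partner arm, which destroys the strand bias and alignment
  asymmetry every real miRNA locus shows. The wobbles keep the hairpin
  stable while making the planted loci look like real ones.
* **5 inverted repeats** — 350-nt arms, 500-nt spacer, emitting a mixed
  21/22/24-nt siRNA population on both strands.
* **1 TAS-like locus** — a 300-nt transcript with an 18-effective-match
  trigger site and phased products D1–D10 plus an off-register and an
  antisense product.
* **TE families** — Gypsy (12 identical copies), Copia, Mutator and CACTA
  (at 1% divergence), with per-family product pools whose weights reproduce
  the 22-nt-reads / 24-nt-uniques inversion in aggregate.
* **rDNA-like tandem array** — five identical 600-bp units with a
  constitutive pool spread over 14/10/12 distinct products at 21/22/24 nt.
* **5 background genes** with exon/intron structure; one carries exonic
  products so the exon-only test has a true positive.

Features are separated by gaps larger than the cluster `max_gap`, so
planted loci map to distinct clusters by construction. Library profiles
follow an eight-library, two-group design — five seed-type libraries with
24-nt-modal length profiles and three vegetative libraries with 21-nt-modal
profiles — with per-feature tissue multipliers (constitutive,
seed-specific, vegetative-specific miRNAs; TE and phased products
seed-weighted).

**Sampling model.** For each read, the insert length is drawn first from
the library's length profile, then a product of that length is drawn
weighted by `base_weight × tissue multiplier`; 10% of reads are random
background; per-base error rate is 0.002. Length-first sampling makes
library size profiles exact by construction, which is what lets the modal
lengths and the TE inversion be asserted rather than hoped for. It has one
sharp consequence: a length class whose product pool is nearly empty
concentrates that library's whole length quota onto a handful of sequences,
and at high depth their single-error variants cross the abundance
threshold by the thousands. The generator therefore keeps every expressed
length class spread over a realistic number of products (the rDNA pool
spread above) and uses an error rate typical of the platform — a realism
constraint on the *generator*, decided during design, not a tolerance
adjustment in the tests. When `background_fraction = 0`, the length profile
is renormalized over lengths that actually have expressible products.

**Identifiability.** Reads are `insert + adapter + filler` truncated to 35
bases. If by chance a full-overlap adapter-prefix match appears upstream of
the true junction, the filler (or failing that the read) is redrawn, so at
`error_rate = 0` every emitted read trims back to exactly its insert and
the collapsed counts equal the simulated truth counts — the exact identity
the end-to-end test asserts.

**What is emulated vs not.** The generator reproduces the *population
structure* (locus classes, size regimes, tissue differences, multi-mapping
bands) — it does not emulate ligation or PCR bias, quality-score
distributions, indel errors, isomiR 5'/3' heterogeneity beyond the planted
products, or genome-scale repeat landscapes. Problem sizes (100-kb genome,
1e5-read libraries) are package defaults chosen so a full run takes on the
order of two minutes on one core; all are configurable.

## 9. Limitations

* The folding score is a stacking-weighted pairing count, not a
  nearest-neighbor free-energy model; thresholds calibrated under it do not
  transfer to RNAfold energies and vice versa.
* Mapping is ungapped; small RNA reads rarely need gapped alignment, but
  true indel variants will be missed.
* The phasing p-value is a conservative upper bound (section 6); it
  controls false positives strictly at the cost of power near the decision
  boundary.
* The annotation rule is intentionally strict (one mismatch at most);
  divergent family members beyond one substitution are reported as novel
  rather than annotated.
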