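---
title: "Methods: virome ecogenomics from bulk metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome ecogenomics from bulk metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virotrace)
```

# Scope

virotrace reconstructs, as tested and reusable code, the analysis chain used
to characterise gut viromes from deeply sequenced bulk metagenomes: ensemble
triage of assembled contigs into viral and non-viral, clustering of viral
genomes into species-level populations (vOTUs), genus-level grouping by
shared protein content, virus–host prediction through four independent
evidence channels, temperate/lytic lifestyle classification, and the
community-ecology statistics used to compare sample groups. Everything
upstream of assembled contigs (read QC, assembly, binning, taxonomy, HMM
annotation, and the external virus predictors themselves) is out of scope:
predictor scores and gene annotations are *inputs*, supplied as plain
tables.

Because the real study inputs are tens of millions of reads per sample and a
stack of external tools, the package ships a seeded synthetic-community
generator with complete planted ground truth. All tests and the acceptance
script run on these communities; what that does and does not demonstrate is
discussed at the end.

# The ensemble screen

Each contig arrives with up to four predictor signals: a VirSorter-style
category (1–6), a DeepVirFinder-style score and p-value, a MARVEL-style
probability (0–100), and a CAT-style annotation summary (a contig-level
viral flag and the fraction of genes classified non-viral). The triage is:

1. **Length/topology gate.** Linear contigs must reach 5,000 bp, circular
   contigs 1,500 bp (circular means an exact direct terminal repeat of at
   least 20 bp; the repeat is counted once when measuring length). Shorter
   contigs are `sub_length`.
2. **Keep gate.** A contig stays in play if any of: a VirSorter category
   (1–6), DVF score ≥ 0.7 with p < 0.05, or MARVEL ≥ 70. CAT evidence alone
   never keeps a contig.
3. **Tier 1 (`high_confidence`).** VirSorter category 1, 2, 4 or 5; DVF
   ≥ 0.9; or MARVEL ≥ 90 — any single strong signal suffices.
4. **Tier 2 (`two_tool`).** Otherwise at least two weaker signals must
   agree: VirSorter 3/6, DVF in [0.7, 0.9) with p < 0.05, MARVEL in
   [70, 90), or CAT support (viral flag, or < 40% of genes non-viral).

Boundary inclusivity follows the printed thresholds literally (≥
everywhere, p strictly < 0.05). The p-value condition is applied in the
Tier-2 DVF band as well as the keep gate — the source text prints it only at
the keep step, and requiring it again is the conservative reading. Missing
values never satisfy a criterion and never error: sparse predictor output is
the norm. The whole rule is verified cell-by-cell against an independently
coded oracle over the exhaustive grid of boundary values.

# Viral populations (species level)

Viral genomes are clustered at **≥ 95% average nucleotide identity over
≥ 80% of the shorter genome**, both thresholds inclusive. The ANI engine
chains exact 15-mer anchors on shared diagonals into ungapped local
segments, extends them base-by-base outward, discards segments under 70%
identity, and combines non-redundant segments: ANI is identity over accepted
columns, AF the fraction of the shorter genome covered. Both strands are
tried; assembly strand is arbitrary. On substitution-only pairs the engine
agrees with full global alignment to within 0.5 percentage points (tested);
it is not intended for heavily rearranged pairs, which real vOTU
dereplication also treats approximately.

Clustering is greedy longest-first: genomes sorted by length descending
(ties by id) join the first representative meeting both thresholds, else
seed a new population. The ordering is canonicalized internally, so the
partition is invariant to input order. Novelty against a reference set asks
whether the representative meets the same 95/80 criterion against any
reference genome.

# Genus-level gene sharing

Representatives are decomposed into ORFs by a deterministic six-frame scan
(every stop-to-stop segment contributes its first-ATG ORF when ≥ 60 aa).
This is a declared simplification of a trained gene caller: it needs no
model and its output is exactly reproducible, which is what the network
layer requires. Proteins are clustered greedily at ≥ 30% identity over
≥ 70% of the centroid (local alignment, BLOSUM62), an analogue of the
published MMseqs2 parameters; amino-acid 4-mer prefiltering keeps unrelated
proteins from ever being aligned.

For each genome pair sharing protein clusters, significance is the
upper-tail hypergeometric probability of sharing at least that many PCs
given each genome's PC count and the PC universe; the edge weight is
−log10 p and edges at weight ≥ 1.0 (p ≤ 0.1, the default of the published
method family) are retained. Viral clusters (VCs) are connected components
of size ≥ 2 — a deliberate, dependency-free stand-in for ClusterONE that
preserves the contract under test: every genome is exactly one of
**clustered** (in a VC), **outlier** (shares genes but no retained edge), or
**singleton** (no shared gene content). Co-clustered reference genomes flag
their VCs but cannot alter relationships among the study genomes, because
edges are pairwise.

# Virus–host prediction

Four channels, each with its own acceptance rule, then a consensus:

* **Prophage**: the full viral contig occurs verbatim (either strand) inside
  a host bin — 100% identity over 100% of the length. To distinguish true
  integration from co-assembly without a web service, an accepted call also
  needs ≥ 1 kb of host flanking sequence on at least one side.
* **CRISPR**: arrays are detected by exact-repeat seeding (repeats 23–47 bp,
  spacers 26–50 bp, minimum two repeat copies; repeats must be exact copies,
  matching the planted data and keeping detection deterministic). Candidate
  arrays are ranked by repeat-copy count before greedy selection so that a
  coincidental seed one base beyond a repeat cannot shadow the real array.
  A spacer hit is accepted at ≥ 95% identity over the whole spacer length,
  ungapped, either strand — i.e. at most ⌊0.05·L⌋ mismatches.
* **tRNA**: tRNAs are located by exact matching against a user-supplied
  library (covariance-model scanning is out of scope; the generator plants
  library members). A shared tRNA must match 100%/100% *and* the same
  (virus, host) pair must already have an accepted prophage call.
* **k-mer**: order-7 Markov models (k = 8, additive pseudocount 1, trained
  on both strands) score each virus by mean per-base log-likelihood; the
  best candidate host's score is referred to a Gaussian null fitted to the
  virus's scores against decoy-host models. Accepted when p ≤ 1e−10 — the
  operational reading of "p = 0", which in the original tool is a
  floating-point artifact — or when p < 0.05 with a concordant accepted
  prophage call.

The consensus keeps all accepted calls as provenance and selects a primary
host by the fixed priority prophage > CRISPR > tRNA > k-mer (ties on host
id). The source text does not state how conflicts were reconciled; this
priority — direct physical evidence first, statistical evidence last — is a
declared design decision, total and deterministic.

# Lifestyle classification

Lysogeny markers come from a gene-annotation table through a
case-insensitive keyword map: integrase/site-specific recombinase,
excisionase, repressor, antirepressor (matched before repressor), ParA/ParB.
Attachment sites are exact direct repeats with core ≥ 12 bp whose two copies
are noncoding (outside every annotated gene), separated by at least half the
contig length, and each within 2 kb of a contig end or an integrase gene;
the search returns nothing on contigs without an integrase. The numeric att
parameters are declared defaults — the source describes att sites next to an
integrase in noncoding sequence but prints no distances — chosen to be
deterministic and testable. A contig is **confident temperate** with an
integrase and an att pair, **candidate temperate** with any marker, else
**no evidence**; confident nests inside candidate by construction.

# Ecology statistics

Counts are normalized as RPKM = count × 10⁹ / (length × total mapped).
Bray–Curtis dissimilarities (vegan underneath) are computed after a
log2(x + 1) transform; a pseudocount of 1 keeps zeros at zero. PCoA is
classical scaling; axes with non-positive eigenvalues are dropped and the
full spectrum reported. ANOSIM R = (mean between-group rank − mean
within-group rank)/(M/2) with a seeded label-permutation test and the
add-one estimator (1 + #{R* ≥ R})/(1 + n_perm), so p is never zero; the
statistic is cross-checked against vegan's implementation in the tests, and
a PERMANOVA pseudo-F wrapper is provided because group tests in this
literature are reported under both names. Shannon diversity uses the natural
log (the vegan convention). Differential abundance uses two-sided Wilcoxon
rank-sum tests (exact for small untied samples) and Welch-t volcano
statistics on log2(RPKM + 1), both BH-adjusted per contrast family; Welch t
without empirical-Bayes moderation is a declared deviation from
edgeR/limma — self-contained and easy to verify by simulation, with
moderation left as future work. Heat-map preparation row-standardizes
(constant rows become zero with a warning) and clusters rows by
complete-linkage Euclidean distance, the defaults of the usual plotting
tool.

# The synthetic communities

The generator emulates the study design: three groups (one control, two
perturbed) of five samples each, a few dozen viral populations over a
handful of host bins, and designated responder taxa at 8-fold (and
1/8-fold) changes. Hosts are sampled from independent order-3 Markov chains
with Dirichlet(1) transition rows, giving each host a distinct, learnable
compositional signature; a host's phages are drawn from the same chain with
5% substitution noise — exactly the assumption that makes k-mer host
prediction possible. Desk-scale sizes are used throughout: host bins of
50–80 kb, phages of 15–35 kb, 200,000 counts per sample; the acceptance
checks use 40 populations × 3 members (10–50 kb) for clustering and 20
replicate communities of 10 hosts for k-mer recovery.

Planted features are written into the sequences and into truth tables with
0-based half-open coordinates: prophage insertions flanked by identical att
cores (with ≥ 1 kb host flanks), CRISPR arrays whose spacers are verbatim
substrings of their target phages, shared tRNAs (only in prophage-linked
pairs, matching the tRNA channel's gating), integrase/marker gene labels,
and direct terminal repeats for circular populations. The DTR length is
drawn once per population, not per member — the repeat is a property of the
genome — which also guarantees the representative stays the longest member.
Population members are substitution-only copies at 1–3%; planted exact
features (att cores, tRNAs) are re-copied into members so the truth tables
stay exact.

Abundance profiles multiply a lognormal base composition by per-sample
lognormal noise (sdlog 0.4) before responder fold-changes and
renormalization; counts are a single multinomial draw per sample. The
per-sample noise models inter-individual variation — without it the three
groups separate perfectly every time, which matches no real gut study. Read
simulation, sequencing error, gaps/indels in planted features, degenerate
CRISPR repeats, and genus-level gene sharing between planted populations
are deliberately absent. Passing tests therefore demonstrate correctness of
the decision rules and estimators under their stated assumptions, not
performance on real assemblies: every detector here sees features planted
to be detectable, and real data add noise sources the generator does not
model.

# Numerical and degenerate-input choices

Thresholds are inclusive as printed; DVF's p is strict. All-zero sample
pairs get Bray–Curtis distance 0 with a warning; all-zero abundance vectors
are an error for Shannon. Constant features give p = 1. ANI between
anchor-free pairs is reported as 0/0 (no homology detected). The report's
host-linked fraction uses screened viral contigs as the denominator — the
universe the consensus table covers. Every stochastic step derives its seed
from the community seed, so a fixed configuration is byte-reproducible end
to end.

# Problem sizes

The shipped defaults (8 hosts, 24 populations + 1 extra member, 15 samples)
run the full pipeline in well under a minute; the clustering and k-mer
acceptance checks each take a few tens of seconds. These sizes were chosen
so the complete property suite exercises every stage at meaningful scale
while remaining comfortable to run repeatedly during development.
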