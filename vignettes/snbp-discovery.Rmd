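---
title: "Discovering sperm nuclear basic proteins: models, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sperm nuclear basic proteins: models, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SNBPscan)
```

## The biological problem

During the final phase of spermatogenesis most histones are stripped from the
sperm genome and replaced by sperm nuclear basic proteins (SNBPs), which
hyper-condense the DNA for packaging into the tiny sperm nucleus. SNBPs come
in several architectures: true protamines (very short, extremely
arginine-rich), protamine-like (PL) proteins (histone-H1 derivatives with an
N-terminal winged-helix (WH) DNA-binding domain and a disordered, highly
basic C-terminal half containing a 30–50 residue Arg/Lys-rich "PL peptide"),
testis-specific histones, and HMG-box proteins. In hymenopteran insects such
as the jewel wasp, fertilization failure has a visible population-level
readout: the species is haplodiploid, so fertilized (diploid) eggs become
females and unfertilized (haploid) eggs become males, and a defective
paternal genome shifts brood sex ratios toward males.

`SNBPscan` implements the computational side of an SNBP hunt as a reusable,
testable pipeline: candidate discovery from tissue-resolved expression and
protein sequence, evolutionary-rate estimation for candidate regions, and
the brood sex-ratio statistics used to score functional knockdowns. A
synthetic-data module generates truth-labelled inputs for every stage, so
the whole pipeline is verifiable without any download.

## The discovery pipeline

Candidates pass through three filters and a classifier; each stage logs a
genes-in/genes-out funnel to standard error.

**1. Tissue exclusivity.** A gene is testis-exclusive when its RPKM in the
male reproductive tract is at least `min_target_rpkm` (default 100) *and*
its RPKM in each of the three other conditions (male carcass, ovary, female
carcass) is at most `max_other_rpkm` (default 5). Both comparisons are
inclusive — the rule is "100 or more" and "no more than 5" — and both
constants are configuration knobs, since the choice of boundary semantics
at exactly 100 and 5 is a judgement call. Missing values are rejected by
the reader rather than imputed: the rule is defined on complete rows.

**2. Basicity.** SNBPs are moderately to strongly basic, so proteins with a
predicted isoelectric point below `min_pi` (default 8.0) are removed; a pI
of exactly 8.0 survives ("below 8.0" is what is removed). The pI comes from
the standard Henderson–Hasselbalch charge balance over the termini and the
ionizable side chains (K, R, H positive; D, E, C, Y negative),

$$Q(\mathrm{pH}) = \frac{1}{1+10^{\mathrm{pH}-pK_{N}}}
 + \sum_{r \in \{K,R,H\}} \frac{n_r}{1+10^{\mathrm{pH}-pK_r}}
 - \frac{1}{1+10^{pK_{C}-\mathrm{pH}}}
 - \sum_{r \in \{D,E,C,Y\}} \frac{n_r}{1+10^{pK_r-\mathrm{pH}}},$$

which is strictly decreasing in pH, so the root is unique and bisection on
pH 0–14 (tolerance $10^{-4}$) is exact for practical purposes. Two
published pKa scales ship in a plain-text table: the protein-optimized IPC
scale (default) and the EMBOSS scale. Which scale a given published pI was
computed under is often unknowable, which is one reason the pI is carried
at full precision internally and rounded to one decimal only in the report.
`X` residues are accepted (counted in length, no ionizable group);
ambiguity codes B/Z/U are rejected rather than inventing chemistry for
them.

**3. GO triage.** Gene ontology terms are matched as case-insensitive
substrings of informal phrases, not GO identifiers, because curated
exclude/include lists are phrase-based in practice. A gene is removed if
*any* term matches *any* exclude phrase (defaults: "electron transport
chain", "mitochondri", "microtubule", "kinase"); of the remainder a gene
is kept if any term matches an include phrase ("DNA", "histone",
"chromatin", "nucleosome", "uncharacterized") *or* if it has no annotation
at all — unannotated genes count as "uncharacterized", an include category.
Exclusion is evaluated before inclusion so a gene with both kinds of terms
is removed. This stage is the one place where the original analysis was
partly curatorial; the term lists are therefore fully exposed in the
configuration.

**4. Classification.** Survivors are assigned one class by ordered rules,
first match wins:

1. **Prot** — length within 50–110 aa and arginine fraction ≥ 0.30;
2. **PL** — a WH domain lying entirely in the N-terminal half
   (domain end ≤ ⌈L/2⌉) and at least one Arg/Lys-rich window *starting* in
   the C-terminal half;
3. **HMG_box** — an HMG-box domain present;
4. **TS_histone** — a histone-fold domain present and pI ≥ `min_pi`;
5. otherwise **non_SNBP**.

Domain calls are inputs from upstream annotators (InterProScan-class
tools), not computed here. The protamine arginine cutoff of 0.30 is an
operating point chosen by this package: descriptions of protamines quote
arginine contents *up to* ~80%, which is an anecdotal ceiling, not a
threshold; 0.30 sits far above any ordinary protein (a uniform-composition
protein has 5% arginine) while catching even arginine-poor protamines. The
midpoint ⌈L/2⌉ makes "N-terminal half" and "C-terminal half" deterministic
on odd lengths. The rule order puts the most specific architecture first;
it, the cutoff, and all interval conventions are configurable or documented
constants.

The Arg/Lys window detector scans every window of every length between
`window_min` (30) and `window_max` (50) residues and keeps windows whose
combined R+K fraction reaches `min_basic_fraction` (default 0.35);
overlapping or adjacent qualifying windows are merged into maximal
intervals. The 30–50 aa range is the documented size of PL peptides; the
0.35 fraction is again an operating point of this package — real PL
peptides run far higher (the merged interval only needs one qualifying
sub-window, so a lower threshold widens intervals rather than creating
false negatives). Note one consequence of merging: an interval can extend
somewhat upstream of a dense basic block when flanking sequence is itself
mildly basic, which is why the classifier conditions on the *start* of a
merged window falling in the C-terminal half.

All residue intervals in the R API and file formats are 1-based and closed
(the Bioconductor/IRanges convention).

## Evolutionary rates

The conserved WH domain versus the rapidly diverging C-terminal half is an
ω (dN/dS) contrast: ω ≪ 1 indicates purifying selection, ω ≈ 1 neutrality.
The package builds in-frame codon alignments by back-translation — each
residue of a protein multiple alignment is replaced by its source codon,
gaps by the `---` codon, with translation verified residue-by-residue under
the standard nuclear code (terminal stop stripped; internal stops are
errors) — and estimates ω two ways:

* **NG86 counting.** Synonymous sites per codon are the per-position
  fractions of single-base changes that preserve the amino acid (changes
  into stop codons count as nonsynonymous so S + N = 3 per codon), averaged
  between the two sequences. Differences between codons are averaged with
  equal weights over all minimal mutational pathways, excluding pathways
  through stop codons (if every pathway is blocked, all are used so counts
  stay defined). Proportions are corrected with Jukes–Cantor,
  $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$. When no synonymous difference is
  observed, ω is reported as undefined (`dS_zero`) rather than infinite;
  $p \ge 3/4$ is flagged `saturated`.
* **Pairwise M0 (GY94) maximum likelihood.** Single-nucleotide codon
  exchanges at rate $\pi_j \kappa^{[\mathrm{ts}]} \omega^{[\mathrm{nonsyn}]}$,
  generator normalized to one expected substitution per codon, transition
  probabilities by eigendecomposition in the π-symmetrized basis (row sums
  checked at $10^{-8}$ and renormalized), and the likelihood
  $\sum_{\text{columns}} \log \pi_i P_{ij}(t)$ maximized over
  $(t, \kappa, \omega)$ in log space within the bounds $t \in (10^{-4}, 50]$,
  $\kappa \in (0.01, 100]$, $\omega \in (10^{-4}, 10]$ from the start point
  $(0.5, 2, 1)$. Estimates at a bound are flagged `boundary` — identical
  sequences, for instance, drive $t$ to its floor. Codon frequencies come
  from the alignment by F3×4 (position-specific nucleotide frequencies with
  add-one smoothing, stops zeroed, renormalized).

A full phylogenetic one-ratio fit over a tree adds little at the scale of a
handful of orthologs and requires a tree that is usually not defendable at
that scale, so the package deliberately implements the pairwise fit plus an
across-pair median (`regionOmega(..., pairs = "all")`) as the desk-scale
analogue, with NG86 as a second, fully oracle-checkable estimator. Columns
containing a gap or ambiguous base in either member of a pair are dropped
for that pair (pairwise deletion), matching common "clean data" practice
and keeping counts well-defined. No ω is ever claimed for a region that
cannot be aligned — in real PL proteins that is precisely the PL-peptide
region, where abundant indels around poly-arginine tracks make codon
homology unreliable; the package scores such regions only qualitatively
(the window detector) and restricts ω to cleanly aligned regions such as
the WH domain.

## Brood sex-ratio statistics

Per-brood female proportion (females / total) is the response; groups are
compared by one-way ANOVA on the raw proportions, with Tukey HSD post-hoc
pairs from the studentized-range distribution (Tukey–Kramer harmonic-mean
adjustment for unbalanced designs). Raw proportions are the default because
that is the natural effect scale for this readout; an arcsine square-root
transform is available (`arcsine = TRUE`) as a sensitivity analysis.
Medians interpolate on even group sizes for determinism. A within-group
variance of numerically zero makes F divergent; this is flagged
(`status = "degenerate"`) instead of producing a meaningless p value.

## What the synthetic data emulates — and what it does not

Every generator is a pure function of its parameters and a seed, and every
planted object enforces a margin on each decision threshold it is meant to
trip, so deterministic stages have exact expected outputs:

* `simulateExpressionMatrix()` — log-normal background RPKM
  (meanlog log 10, sdlog 1.5, a typical right-skewed RPKM shape) across all
  four conditions; background rows that would pass, or come within the
  margin of passing, the exclusivity rule are re-drawn; planted genes sit
  at least `margin` beyond both thresholds. Consequently filter recall and
  precision are exactly 1 by construction — which validates the *rule
  implementation*, not the biological sensitivity of the thresholds.
* `simulateSnbpProteome()` — PL proteins of 200–250 aa with an N-terminal
  WH interval, a planted window 0.15 above the basic-fraction threshold
  placed deep enough in the C-terminal half that merge-extension cannot
  drag its start before the midpoint, scattered cysteines, and a
  guaranteed pI ≥ 8.2 under the configured scale; protamines of 55–105 aa
  at arginine fraction 0.4–0.7; HMG-box and TS-histone architectures via
  their domain rows; decoys with flat-Dirichlet composition re-drawn away
  from the protamine arginine cutoff.
* `simulateCodonEvolution()` — exact stochastic (Gillespie) simulation
  under the normalized GY94 generator, deliberately sharing no linear
  algebra with the estimator, on a star tree with branch length t/2 per
  tip. Stops can never arise because their rates are zero. One subtlety
  this surfaced: under ω = 0 every substitution is synonymous, yet NG86
  can still report a small Nd, because its equal-weight pathway average
  across multi-hit codons includes nonsynonymous routes between codons
  whose true history was purely synonymous (TTA↔CTC, both leucine, is the
  minimal example). The faithful invariant — asserted in the tests — is
  that every simulated row still encodes the ancestral protein.
* `simulateBroods()` — Poisson brood sizes (minimum 1) and binomial female
  counts at the group's probability. The default study conditions are
  three groups of 21 broods (63 total, matching the between/within degrees
  of freedom 2 and 60 of the real design) of mean size 30, at female
  probabilities 0.85 / 0.54 / 0.84 — an untreated control, a strong
  knockdown and a subtle one.

Real data differ in ways the generators do not imitate: RPKM values are
correlated across tissues and genes, real codon usage is biased (no attempt
is made to imitate wasp genome composition), brood counts are
overdispersed relative to the binomial (the real F statistic is far below
what a pure-binomial simulation of the same medians produces), and GO
annotation is incomplete and noisy in ways a term pool cannot capture.
Passing tests therefore demonstrate correctness of the algorithms under
their stated models, not field performance of the thresholds.

## Numerical choices and degenerate inputs

* Bisection tolerance $10^{-4}$ pH; the dense-grid oracle comparison in the
  test suite bounds the realized error at 0.01.
* M0 convergence tolerance $10^{-6}$ in log-likelihood; optimization in log
  parameter space with box bounds; `boundary` status rather than silent
  clipping.
* Sequences shorter than `window_min` yield an empty window set with a
  warning, not an error; a one-column ω slice returns `dS_zero`/`saturated`
  rather than a number.
* Report ordering is total: descending target RPKM, ties broken
  lexicographically by gene id.
* All simulation seeds are 32-bit integers; generators restore the
  caller's RNG state.

## Validation scales

The test suite and the acceptance script run entirely on synthetic or
shipped plain-text inputs at these problem sizes, chosen to make each
check statistically meaningful at interactive runtimes: 10,000-gene
matrices with 50 planted positives over 5 seeds for the filter; 100 random
proteins against a 0.001-pH grid oracle for the pI solver; 200 random
10–30-codon pairs against a brute-force pathway enumerator for NG86; 20
seeds × 1000 codons at ω ∈ {0.15, 0.46, 1.0} for estimator recovery
(medians within ±30% of truth for both estimators); 40 replicates of a
purifying-vs-neutral region contrast; and 500 null / 100 alternative
brood-table replicates for the size and power of the ANOVA, with Tukey p
values checked against a 10,000-draw Monte-Carlo studentized-range oracle
to 0.01.

## Known limitations

* The GO triage reproduces a partly curatorial step; on real annotations
  the outcome depends on the curator's term lists, so the historical
  13-gene candidate list is not a mechanical target of this package.
* Pairwise M0 with an across-pair median is not a tree-aware fit; for rich
  ortholog sets a phylogenetic codeml-style analysis remains preferable.
* No positive-selection site tests (M1a/M2a, branch-site) are provided —
  at the ortholog counts typical of SNBP families they are underpowered —
  and no structural disorder prediction: the C-terminal-half heuristic
  stands in for disorder annotation.
* RPKM computation, read mapping, ortholog discovery, protein alignment
  and domain annotation are all upstream of this package and consumed as
  inputs.
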