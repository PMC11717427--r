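---
title: "Methods and design notes for genetriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for genetriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetriage)
```

# Scope

`genetriage` implements a two-stage analysis: (1) meta-analysis of many
published gene lists to prioritize regulated-but-understudied genes, and
(2) triage of predicted protein-dimer models into interaction calls. This
vignette records the models, the tunable parameters with their defaults,
what the synthetic generators do and do not emulate, and the design
decisions taken where the procedure was genuinely open.

# Gene-list ingestion

Each source table carries gene tokens with optional raw and adjusted
P-values. The significance filter retains a row when its governing value
is `< alpha` (default 0.05) *or when it carries no value at all*: many
published lists are pre-filtered by their authors and report no per-gene
statistics, so dropping value-free rows would silently discard whole
studies. When both a raw and an adjusted value are present the adjusted
one governs by default — it is the stricter, more standard choice — and
the precedence is exposed via `prefer=` because the alternative reading is
defensible. Gene identifiers are opaque, case-sensitive strings; alias
resolution is the caller's responsibility (an `AliasMap` is consumed, never
fetched), with unresolved tokens kept, dropped, or escalated per policy.

# The regulation score

For lists $i = 1 \dots n$ of sizes $T_i$ and a gene set $G$,
$r_g = \sum_i S_i / T_i$ with $S_i = |G \cap \text{list}_i|$. The printed
definition is set-level; ranking individual genes "by $r_g$" requires a
per-gene reading. We adopt

$$r(j) = \sum_{i \,:\, j \in \text{list}_i} \frac{S_i}{T_i},$$

i.e. each list votes for its members with its selectivity-weighted overlap
with the culled top set. This reduces to the set-level sum when restricted
to a single gene's lists, and summing over the set gives the checkable
identity $\sum_{j \in G} r(j) = \sum_i S_i^2 / T_i$, which the test suite
asserts against a brute-force double loop on random corpora. The
pure-selectivity alternative $r(j) = \sum 1/T_i$ (ignoring the rest of the
set) is available via `method = "selectivity"`; whether the original
analysis used one or the other cannot be settled from the text alone, so
both are implemented and labeled. Frequency-based culling precedes
scoring, and all ties break lexicographically on gene id so results are
reproducible without seeds.

# Co-occurrence: Jaccard, HMI, communities

Presence/absence vectors over the $n$ lists are compared by Jaccard
distance ($d_J = 1 - |A \cap B| / |A \cup B|$; a metric, property-tested)
and by *historical mutual information*: the mutual information of the
2×2 contingency, normalized symmetrically. The cited normalization is not
printed, so the package defaults to symmetric uncertainty
$2I/(H_A + H_B)$ — the most common symmetric form — with the geometric
alternative $I/\sqrt{H_A H_B}$ behind `normalization =` (both coincide at
0 and 1). Conventions: $0 \log 0 = 0$, and HMI is 0 when both marginals
are constant. Dendrograms use average linkage (UPGMA via
`stats::hclust`), serialized to Newick through `ape`.

The HMI graph links genes whose distance $1 - \mathrm{HMI}$ is at most
0.9, *inclusive* ("0.9 or less" is the stated rule). Girvan–Newman
community detection removes the highest-betweenness edge, recomputing
betweenness after every removal, and returns the partition of the removal
sequence maximizing Newman modularity — the stopping rule is unstated in
the source procedure, and max-modularity is the standard choice.
Betweenness is computed on the unweighted topology while modularity uses
HMI edge weights (configurable); betweenness ties break on the
lexicographically smallest endpoint pair, making the output deterministic.
The 6-node two-clique test verifies the returned modularity equals a
brute-force maximum over all 203 partitions.

# Overlap simulation

The chance that a uniform $T$-subset of an $N$-gene genome misses a fixed
$g$-gene set is $\binom{N-g}{T}/\binom{N}{T}$; `p_overlap_analytic()`
evaluates the complement through log-gamma arithmetic so it is stable at
$N = 20{,}000$. The Monte-Carlo counterpart mirrors the boxplot design of
the motivating figure: each of `runs` (default 100) runs estimates
$P(S_i > 0)$ from `lists_per_run` lists. What one "run" aggregates is not
stated in the source; we default `lists_per_run = 398`, the corpus size,
and expose it rather than guess silently. Internally the per-list overlap
count is drawn with `rhyper()` — the count of top-set members in a uniform
$T$-subset is exactly hypergeometric, so the estimator is
distributionally identical to materializing subsets and much faster.

The preferential-attachment generator grows lists sequentially, sampling
genes without replacement with weight (current occurrence count +
`attachment_strength`). The exact supplementary rules are not printed;
this count-plus-smoothing rule is declared in the interface and is a
documented stand-in. Its two limits are tested: strength $\to \infty$
approaches uniform sampling (chi-square calibration across seeds), and
strength 0 with a single seeded occurrence is degenerate rich-get-richer.

# Structure triage

**Inputs.** PDB or minimal mmCIF coordinates (exactly two chains, Cα atoms
required), a square PAE matrix in JSON (bare array or under
`pae`/`predicted_aligned_error`), and flat score JSON
(`iptm`, `ptm`, optional `disorder_frac`, `version`). PAE rows/columns are
chain A residues then chain B, 1-based per chain.

**Criteria.** Ranking score: $0.8\,\mathrm{ipTM} + 0.2\,\mathrm{pTM}$
(AF2-like) or with $+0.5\,\mathrm{disorder}$ (AF3-like), reported without
clamping. A pair is constrained when Cα distance $< 6$ Å (strict) and
$\max(\mathrm{PAE}_{ij}, \mathrm{PAE}_{ji}) < 5$ Å (strict): PAE is
asymmetric and "maxPAE" is read conservatively as the symmetric maximum.
All-atom minimum distance is available for sensitivity analysis, since the
original distance criterion is stated as inter-Cα only in some places.
Verdicts: v1 requires ranking $> 0.6$ and $\ge 20$ distinct constrained
prey residues ("a minimum of 20" read inclusively); v2 requires ranking
$> 0.6$ and $n_\mathrm{bait} n_\mathrm{prey} > 100$ (strict, as printed).
Both are recorded independently on every call.

**Buried area.** $\tfrac12(\mathrm{SASA}_A + \mathrm{SASA}_B -
\mathrm{SASA}_{AB})$ over the mutually constrained residues, following the
ChimeraX `buriedarea` definition the procedure invokes; SASA by
Shrake–Rupley quadrature with 960 deterministic golden-spiral points and a
1.4 Å probe, Bondi van der Waals radii by element (1.8 Å fallback). The
single-sphere value is within 2% of $4\pi(r+1.4)^2$ at this point count.
The normalized value divides by the product of the full chain lengths;
any further uniform display scaling is left to presentation.

**Convergence.** Models are superposed by Kabsch least squares on the
anchor chain's Cα atoms and RMSD is reported over the partner chain — the
reading of the convergence plot in the source — with whole-complex RMSD
behind `scope = "complex"`. **Concordance** between two pipelines'
calls compares constrained prey-residue footprints by Jaccard overlap; the
0.25 "similar interface" cutoff is a package invention (the source never
quantifies similarity), is inclusive at the boundary, and is reported with
every verdict.

# Reading-frame scan

`six_frame_longest()` reads "uninterrupted stretches" as stop-to-stop runs
of the standard genetic code, not ATG-initiated ORFs — the motivating
peptide lengths are reported without start-codon language — with
`require_atg = TRUE` covering the alternative. Codons containing N
translate as X and never terminate a run; ties resolve to the 5′-most run;
minus-strand spans are mapped back to input-strand coordinates. The
scanner is validated against an exhaustive codon-run oracle and a
reverse-complement symmetry property. Reproducing the four published
pseudogene peptide lengths requires externally downloaded sequences and is
deliberately out of scope.

# Synthetic data: what a green test establishes

`gen_list_corpus()` emulates a literature corpus: log-uniform list sizes
over 10–2,000 genes (the heterogeneity of published tables), planted
co-occurring blocks with a stated per-list probability, optional hub genes
with elevated inclusion rates, uniform background fill. Defaults state the
emulated world: a 20,000-gene universe and 398 lists. It does **not**
emulate technique-correlated biases, list-size/gene-frequency coupling, or
annotation drift — so a green clustering test establishes correct recovery
of planted independence structure, not robustness to real-literature
confounding.

`gen_dimer_fixture()` writes loadable PDB/JSON fixtures whose constrained
pairs under default thresholds equal the planted set exactly. Chains are
idealized helical Cα traces (3.8 Å consecutive spacing, 1.42 Å rise —
helical rather than straight so superposition anchors are never collinear,
which would make the Kabsch rotation ill-posed). Each planted prey residue
sits on a 5 Å arc around its bait partner (up to 8 per arc, the geometric
capacity; infeasible requests error out), bulk non-contact residues stay
≥ 12 Å away, and the PAE channel (signal 3 Å / noise 20 Å) discriminates
planted from incidental proximity — residues adjacent to a contact site
may fall within 6 Å and are excluded by PAE alone, exactly as the pair
criterion allows. One carbon sphere per residue stands in for side chains
in SASA tests; the generator does not emulate AlphaFold's actual error
structure beyond threshold-respecting signal/noise levels. A
generation-time self-check re-measures every planted distance.

`gen_pseudogene_seq()` plants a stop-free run of exact codon length in a
chosen frame: run codons come from {TTA, CTA, TCA} (antisense codons are
all stops, silencing the reverse strand), an 8-codon phase-breaker block
interrupts both shifted forward phases mid-run, and the background tiles
stop cassettes covering all six phases. Planted runs must be ≥ 9 codons so
they dominate the ≤ 8-codon background gaps; generation re-scans the
sequence and fails loudly rather than emit an unverified fixture.

# Numerical choices and degenerate inputs

- Tie-breaks: lexicographic everywhere (gene ranking, edge removal), so no
  seed is needed for determinism of the deterministic stages.
- Empty inputs: filtered-empty gene lists are flagged and excluded from
  the matrix; empty constrained sets yield zero area and false verdicts;
  empty graphs yield empty partitions and valid (empty) GraphML.
- Binomial ratios via `lchoose`; mutual information guards tiny negative
  rounding; HMI capped at 1.
- PDB coordinates are written and parsed at 3 decimals, so distances
  carry ~2 mÅ quantization; tests bracket thresholds accordingly.

# Known limitations

- The per-gene $r$ interpretation and the HMI normalization each have one
  labeled alternative; conclusions sensitive to either choice should be
  checked under both switches.
- Girvan–Newman recomputes betweenness after every removal
  ($O(VE^2)$-ish); intended for the few-hundred-node graphs this analysis
  produces, not for large networks.
- The mmCIF reader handles plain whitespace-delimited `_atom_site` loops
  only (no quoted tokens or multi-line values) — sufficient for
  prediction-pipeline outputs, not a general CIF parser.
- The Shrake–Rupley implementation is quadratic in atoms per selection;
  constrained-residue selections are small by construction.
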