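---
title: "Methods: mtDNA forensics for caviar market surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA forensics for caviar market surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`caviarid` reconstructs, as tested code, the desk side of a DNA-barcoding
market survey for black caviar: identify the maternal species in each
purchased tin from mitochondrial markers, decide per lot whether the
identification is consistent with the trade label, and summarize
mislabeling at the survey level. This vignette is the package's account of
the science: the models, the decision rules, the tunable parameters, what
the synthetic data do and do not emulate, and the choices made where the
design was genuinely open.

## The substitution model and likelihood engine

Identification rests on a general time-reversible (GTR) nucleotide model
with discrete-Gamma rate heterogeneity. The instantaneous rate matrix has
off-diagonal entries $q_{ij} = s_{ij}\,\pi_j$ (six exchangeabilities
$s_{ij}$, stationary frequencies $\pi$), diagonal set so rows sum to zero,
and is normalized so that $-\sum_i \pi_i q_{ii} = 1$: branch lengths are
then expected substitutions per site. Among-site rate variation uses $K$
equal-probability Gamma categories (default $K = 4$); each category is
represented by its mean, computed from the incomplete-Gamma identity, so
the category rates average exactly 1. The mean-of-quartile construction
(rather than the median) is the standard discretization and keeps the
process's expected rate equal to the homogeneous model's.

Tree likelihoods are computed by Felsenstein pruning over compressed site
patterns. Transition probabilities come from the eigendecomposition of the
symmetrized rate matrix
$B = \Pi^{1/2} Q\, \Pi^{-1/2}$, computed once per model and reused for
every branch and rate category. Numerical choices:

- **Underflow**: partial likelihoods are rescaled by their per-site column
  maximum at every internal node; the log scalers accumulate and are added
  back on the log scale. The Gamma mixture is combined per site with a
  log-sum-exp.
- **Missing data**: gaps and every IUPAC ambiguity code contribute a
  partial likelihood of 1 for each compatible state. Simulation never
  emits ambiguity codes; real chromatogram ambiguity enters only through
  input sequences.
- **Optimizers**: branch lengths are optimized coordinate-wise with Brent
  line search on $[10^{-8}, 10]$ substitutions/site, sweeping edges until a
  pass gains less than $10^{-6}$ log-units. The Gamma shape is optimized
  on $\log \alpha \in [\log 0.02, \log 100]$. When a bound achieves a
  log-likelihood within 0.5 units of the interior optimum the bound is
  reported and flagged: for effectively rate-homogeneous data the profile
  in $\alpha$ is flat, and half a log-unit is below any conventional
  significance threshold, so the fit is reported as "at the boundary"
  rather than pretending an interior estimate is meaningful.

The engine is validated in the test suite against exhaustive enumeration
of internal-node states on small trees (≤ 5 tips, ≤ 30 sites, tolerance
$10^{-8}$), against an independent GTR+Γ implementation, against the
closed-form Jukes–Cantor distance $-\tfrac{3}{4}\log(1 - \tfrac{4p}{3})$
for two-taxon trees, and against numerical quadrature of the Gamma density
for the category rates.

**Tree search** is deliberately modest: restarts (default 10) from one
neighbor-joining tree and stepwise-addition maximum-parsimony trees with
random addition orders, each climbed by nearest-neighbor-interchange with
branch-length re-optimization until no neighbor improves the
log-likelihood by more than $10^{-4}$. No SPR moves, no partitioned or
codon models. Bootstrap support resamples alignment columns, rebuilds a
tree per pseudoreplicate, and reports for each internal edge of the best
tree the percentage of bootstrap trees whose bipartition set contains that
edge's tip bipartition — the "filter the best tree through the bootstrap
swarm" convention, invariant to rooting and tip order.

## Identification of a query sequence

1. **Best-hit screen.** Smith–Waterman local alignment (match +2,
   mismatch −3, gap open 5, extend 2 — MegaBLAST-like defaults,
   configurable) against every reference sequence of the marker; hits are
   ranked by score with ties broken by reference id.
2. **Placement.** The query is threaded into the reference alignment via
   its best hit (query-inserted columns discarded), then attached at the
   midpoint of every reference-tree edge with the pendant branch length
   optimized; internal branch lengths stay fixed. Per-edge rootward and
   tipward conditional likelihoods are precomputed once per reference
   panel, so each pendant evaluation costs one 4×4 matrix product — this
   is what makes surveys of thousands of eggs tractable. Edges are first
   scanned on a coarse pendant grid ($10^{-4}$, 0.005, 0.03) and the five
   most promising refined by line search; likelihood-weight ratios are
   reported across all edges.
3. **Calling.** Candidate species are those on the tipward side of the
   best edge plus any hit within the tie margin (default 0.5 percentage
   points) of the top identity. A single candidate gives a species call —
   unless it belongs to a species group that is unresolvable at this
   marker, in which case the group is called. Multiple candidates spanning
   exactly one such group also give the group; anything else is
   `unresolved` (a valid outcome, with a reason code). No call of any kind
   is made when the top identity falls below the identity threshold
   (default 98%, the low end of the identity range a confident barcode
   match produces).

Species groups encode known marker limits: the Russian-sturgeon complex
(*A. gueldenstaedtii*, *A. naccarii*, *A. persicus*) is unresolvable at
cytb and the D-loop and is reported as "*A. gueldenstaedtii/A. naccarii*"
(*A. persicus* is never called at species level); *Scaphirhynchus* is
unresolvable at all three markers and reported at genus level. *A. baerii*
is resolvable at both cytb and the D-loop and is not grouped. Where
best-hit identity and placement disagree, placement wins; both are kept in
the call's evidence.

## The per-lot decision workflow

One egg per tin is identified first, with marker escalation:

- **cytb** is always attempted first.
- **D-loop** follows for every osetra-labeled lot and whenever the cytb
  call lands in the Siberian/Russian sturgeon complex (*A. baerii*,
  *A. gueldenstaedtii*, *A. naccarii*, *A. persicus* — species or group
  call). A resolvable D-loop call overrides the cytb call within the
  complex; an unresolved or failed D-loop leaves the cytb call standing.
- **cox1** is the fallback only when neither cytb nor the D-loop yielded a
  sequence (it catches non-sturgeon substitutes such as pike roe).
- All markers failing is an extraction/amplification failure — an input
  fact, never inferred from sequence content.

A label-consistent call closes the lot at one egg. An inconsistent call
triggers confirmation with **every remaining egg in the lot record**; at
least 9 additional resolvable eggs give confirmation status "confirmed",
fewer give "partial", none give "unconfirmed" — the verdict stands
regardless. The verdict is `mislabeled` when every resolvable confirmatory
egg contradicts the label and `mixed` when consistent and inconsistent
eggs co-occur; mixed lots count as mislabeled in headline statistics but
are reported separately. (Real confirmations used "at least nine more
eggs" but published egg counts reach 14, so the number of confirmatory
eggs is controlled by the lot record, not hard-coded at nine.) Verdicts
are invariant to egg order, and no lot is ever flagged on single-egg
evidence while further eggs are available.

Label consistency closes over groups: a species call is consistent when it
lies in the label's allowed set expanded by mtDNA-indistinguishable group
members at the call's marker; a group call is consistent when any member
is allowed. The default label policy maps beluga → *Huso huso*, sevruga →
*A. stellatus*, osetra → {*A. gueldenstaedtii*, *A. persicus*,
*A. baerii*}, white → *A. transmontanus*, paddlefish → *P. spathula*,
hackleback → *S. platorynchus*, american → the three North American
species, and unrecognized labels → any acipenseriform (so only
non-sturgeon substitutes can contradict a generic "black caviar" label).
An explicit claimed species on the label narrows its market set to that
species. Genus-level *Scaphirhynchus* calls are treated as consistent with
hackleback labels, reflecting that mtDNA cannot do better there.

**Haplotype counting**: distinct sequences at the primary confirmatory
marker (cytb when available, otherwise the deciding marker), after
trimming to the region covered by every sequence and masking columns with
ambiguity codes — sequences differing only at masked or uncovered
positions are one haplotype. Multiple haplotypes in one tin indicate
pooling of roe from several females.

## Survey statistics

The headline rate is `100 · mislabeled / tested`, where the denominator is
caviar lots with a resolvable final call: extraction failures, unresolved
lots and non-caviar samples (the meat sample) are excluded. This matches
the survey convention of reporting *n* = 90 testable lots out of 93
purchased samples. The 95% CI is exact Clopper–Pearson (inverted binomial
tails, via `binom.test`). Breakdowns by channel or year partition the same
testable set and always reconcile with the overall summary.

The two-period comparison takes both periods as plain counts — the
1995–1996 baseline (19%, *n* = 95, i.e. 18/95) is an input, never
recomputed — and reports the difference in percentage points, Fisher's
exact test (the hypergeometric 2×2 conditional test), and a CI for the
difference by Newcombe's method, combining the two Wilson score intervals.
Newcombe was chosen because the Wald interval misbehaves at the small
counts typical of these surveys; the choice is documented here and in the
function's help.

## The synthetic market and what it does (not) show

`generate_references()` simulates the reference panel: each species tip of
a 12-taxon acipenseriform phylogeny (plus pike as substitute roe) is
expanded into 2 reference tips (pendant $5 \times 10^{-4}$ subs/site) and
6 market-haplotype tips (pendant 0.004), and sequences are evolved along
the tree per marker. Marker conditions: lengths 620/500/650 nt for
cytb/D-loop/cox1; the D-loop evolves at twice the cytb rate and cox1 at
0.8×; Gamma shapes 0.224 (cytb) and 0.345 (D-loop) — the values fitted to
the real survey's alignments — and 0.25 for cox1; fish-mtDNA-like base
frequencies (A 0.28, C 0.27, G 0.16, T 0.29) with transition-biased
exchangeabilities. Group unresolvability is *emergent*: complex members
sit on branches of $\sim 10^{-3}$ subs/site, so their simulated barcodes
are nearly identical and the caller lands in the tie margin, exactly as
with real sturgeon mtDNA.

`generate_survey()` draws each lot's label from the survey's market
composition, a mislabeling Bernoulli event at the true rate (default
0.10), the true species from the label template or a label→substitute
table mirroring the substitutions actually seen in trade (paddlefish,
sterlet or Russian sturgeon as "sevruga"; the complex or Siberian sturgeon
as "beluga"; *baerii* ↔ *gueldenstaedtii* swaps under osetra labels; pike
as a generic substitute), 10–14 eggs, occasional pooling (probability
0.15; two, rarely three, haplotypes), and independent per-egg per-marker
dropout (3–5%). Ground truth is recorded before dropout as "true species
outside the label's allowed set". Random streams are derived
hierarchically (survey → lot → egg) with an overflow-safe integer mix, so
one lot's draws never perturb another's — identical seeds reproduce
surveys byte for byte.

Egg sequences are drawn from the finite per-species haplotype pool rather
than re-simulated per egg. That is both realistic (market mtDNA diversity
is limited) and what makes large validation runs cheap, since per-sequence
identifications are memoised on the reference panel.

What passing these tests shows: the decision logic, escalation rules,
confirmation arithmetic and statistics behave correctly when sequence data
carry the signal the markers are known to carry. What it does not show:
robustness to real-world sequence pathologies — chromatogram noise,
heteroplasmy, NUMTs, primer-site variation, partial reads — none of which
the generator emulates; dropout is an abstract flag, not a chemistry
model. Accuracy numbers from synthetic runs are properties of the study
conditions above, not field performance guarantees.

The encoded 2006–2008 New York City survey is the strongest fixture: all
93 samples with their labels, channels, years, the two failed extractions,
the three D-loop amplification failures among osetra lots, the cox1-only
pike lot, and the nine substitutions with their published egg and
haplotype counts. Its sequences are synthetic (drawn from the generated
pool to match each lot's documented identification — the real reads are
not printed anywhere), so it validates the workflow's bookkeeping, not the
wet lab: the pipeline must recover 90 testable lots, 9 mislabeled (10.0%),
all on the internet channel, 32 D-loop-sequenced lots, and every per-lot
identification, egg count and haplotype count.

## Problem sizes and open choices

Validation runs use: 100 random enumeration-oracle instances (≤ 5 tips,
≤ 30 sites); Gamma-shape recovery at 8 tips × 2000 sites; 200 simulated
90-lot surveys for rate recovery; 20 surveys for sensitivity; 50 clean
50-lot surveys for specificity. These sizes give Monte-Carlo error well
inside the asserted bands while keeping a full run in minutes on one core.

Choices made where the design was open, and why:

- **Published LnLik/α values are not asserted.** The real survey's
  alignments (trimming, length) are not published, so its exact tree
  likelihoods and fitted shapes are not reproducible from deposited
  accessions alone; the shapes are used as simulation defaults instead.
- **D-loop counting.** "Escalated to D-loop" counts lots that *yielded* a
  D-loop sequence; three osetra lots whose D-loop failed to amplify are
  escalated but not counted, which is how a 33-osetra-lot survey reports
  32 D-loop lots.
- **Mixed lots** (not observed in the real surveys) count as mislabeled in
  the headline rate — the conservative reading — and are reported
  separately so the choice is visible.
- **Conflict between identity and placement** is resolved in favor of
  placement, configurably; both pieces of evidence are retained.
- **Claimed-species closure**: "Osetra (*A. gueldenstaedtii*)" identified
  as the group is not flagged, because the marker cannot distinguish the
  claim from its group siblings; flagging would manufacture mislabeling
  from marker limits.

## Limitations

mtDNA is maternal: hybrids are invisible by construction, and
farmed-versus-wild origin, population assignment and harvest-year legality
are out of scope. *A. persicus* cannot be assigned at these markers, and
*Scaphirhynchus* congeners cannot be separated, so label fraud inside
those groups is undetectable. The tree search is a small, documented hill
climber, not a replacement for production ML software on large panels.
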