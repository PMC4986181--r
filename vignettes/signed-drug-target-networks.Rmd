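---
title: "Signed drug-target networks: coherence, synergy and side-effect scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed drug-target networks: coherence, synergy and side-effect scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtnet)
```

## The model

A drug-target network is a bipartite graph: one node class for drugs, one
for targets, an edge for every recorded action of a drug on a target. Many
recorded modes of action admit a natural direction — agonists, activators,
inducers push a target's activity up; inhibitors, antagonists, blockers push
it down — so each edge can carry a sign: `+1` for activating-like actions,
`-1` for inhibiting-like ones, `0` where no direction is defensible
("binder", "modulator", "antibody", ...). The shipped vocabulary classifies
36 common mode-of-action labels into 8 positive, 12 negative and 16
unclassifiable; matching is case-insensitive with whitespace collapsed, and
unknown labels degrade to sign 0 with a warning so that extracts using novel
vocabulary still load.

Each edge additionally carries a `pharmacological` flag marking the intended
(on-target) action. The flag is a property of the *edge*, not of the target:
the same protein can be the designed target of one drug and an off-target —
a side effect — of another. Signed off-target edges are the network's
operational notion of a drug's side effect.

When two drugs act on a common target, their joint action is **coherent**
if the signs agree — the second drug reinforces the first — and
**incoherent** if they oppose, in which case the effects tend to compensate.
Everything in this package is built from that binary classification.

## Pair-level statistics

For a drug pair $(i,j)$, `enumerate_shared_pairs()` counts the shared signed
targets by sign pattern, $c_{ij}^{++}, c_{ij}^{--}, c_{ij}^{+-}$, with
$c_{ij}$ their sum, and splits them into shared *pharmacological* actions
$p_{ij}^{\cdot\cdot}$ (targets pharmacological for **both** drugs) and shared
*off-target* actions $s_{ij}^{\cdot\cdot}$ (targets pharmacological for
**neither**). Per-drug totals $t_i$ (signed targets), $p_i$ (signed
pharmacological targets) and $s_i = t_i - p_i$ (signed off-targets) are
carried along.

A shared target that is pharmacological for exactly one drug of the pair is
deliberately counted in $c_{ij}$ and in the derived $s_{ij} = c_{ij} -
p_{ij}$, but in neither family of score numerators. Such a target is the
principal action of one drug and a side effect of the other; including it in
the side-effect numerator while it is absent from the other drug's
off-target count $s_i$ would let the side-effect score escape $[-1, 1]$, a
bound the scores are meant to satisfy by construction. Restricting the
numerators to targets off-target for both drugs restores the bound exactly
and leaves every worked example below unchanged (none involves such a
mixed-flag target).

The network-wide **coherence probability** is

$$\rho = \frac{\sum_{ij} \left(c_{ij}^{++} + c_{ij}^{--}\right)}{\sum_{ij} c_{ij}},$$

the fraction of pairwise shared-target *actions* that are coherent. A
related but distinct quantity — the fraction of *pairs* with at least one
coherent action — is reported alongside under a separate name, since the two
are easily conflated when pairs share several targets.

### Enrichment testing

Whether a particular pair is unusually coherent is tested against a binomial
null: with $\xi = c_{ij}^{++} + c_{ij}^{--}$ coherent actions out of
$c_{ij}$, the one-sided upper tail $P[X \ge \xi]$, $X \sim
\mathrm{Bin}(c_{ij}, \rho)$, is the coherent-enrichment p-value, and
symmetrically $P[Y \ge c_{ij}^{+-}]$, $Y \sim \mathrm{Bin}(c_{ij}, 1-\rho)$,
for incoherent enrichment; a pair is called at the smaller p-value below
`alpha` (default 0.05, per-pair, uncorrected; a Benjamini–Hochberg mode is
available via `adjust = "BH"`).

The cumulative-binomial formula this test derives from is printed in its
source with $(1-\rho)$ on the running index and the p-value as one minus the
lower tail, which taken literally tests the wrong tail for coherent
enrichment. The package implements the standard upper-tail orientation,
which matches the test's stated purpose; `mode = "printed"` reproduces the
literal algebra for anyone wanting to compare.

$\rho$ is computed once over the whole network and reused for every pair;
the focal pair is not excluded. For the large networks this test is meant
for, a single pair's contribution to $\rho$ is negligible, and a global
$\rho$ keeps every pair tested against the same null.

### The null model

`build_null_model()` keeps each edge's drug endpoint, sign and
pharmacological flag and redraws its target uniformly from the original
target set, resampling collisions so the result is again a simple bipartite
graph. Every drug's (degree, positive, negative) triple is preserved
exactly; target degrees collapse toward uniform. On a real-scale network the
ensemble (default 100 realizations) shows how much of the observed pair
overlap is forced by the drug-side degree/sign sequence alone — typically
far less than observed, and with pairs rarely sharing more than 4 targets.

## Length-4 cycles

Two drugs sharing two targets close an undirected 4-cycle. Per-target
coherence classifies the cycle as fully **coherent**, **mixed** or fully
**incoherent**; the six canonical sign patterns are `(+,+/+,+)`,
`(+,+/-,-)`, `(-,-/-,-)` (coherent), `(+,+/+,-)`, `(+,-/-,-)` (mixed) and
`(+,-/+,-)` (incoherent). Cycle *parity* — the product of the four signs —
couples to coherence: coherent and incoherent cycles are positive, mixed
cycles negative, a fact tested exhaustively over all 16 sign assignments.
Enumeration counts each unordered (drug pair, target pair) square once, so a
pair with $k$ shared targets contributes $\binom{k}{2}$ cycles; the counts
follow combinatorially from each pair's $(c^{++}, c^{--}, c^{+-})$ split,
and fractions are formed from exact integer counts only at reporting time.

## Synergy and side-effect scores

For pairs overlapping on pharmacological targets, the **synergistic score**
of drug $i$ given $j$ is

$$a_i(j) = \frac{\left(p_{ij}^{++} + p_{ij}^{--}\right) - p_{ij}^{+-}}{p_i} \in [-1, 1],$$

coherent minus incoherent shared pharmacological actions over drug $i$'s
pharmacological target count. Positive means mutual reinforcement on the
principal targets; the shared numerator forces $\mathrm{sign}(a_i(j)) =
\mathrm{sign}(a_j(i))$, while magnitudes differ with $p_i \ne p_j$. The
source formula for this score is printed with the incoherent count first,
which contradicts both its stated semantics and its own worked example (two
drugs sharing one coherent pharmacological target score $a = 1$, not $-1$);
the package treats that as a typographic sign error and implements
coherent-minus-incoherent.

The **side-effect score**

$$b_i(j) = \frac{s_{ij}^{+-} - \left(s_{ij}^{++} + s_{ij}^{--}\right)}{s_i} \in [-1, 1]$$

has the opposite orientation on purpose: on off-targets, *opposition* is the
desirable outcome, since incoherent actions tend to cancel the unintended
effect. $b_i(j) = 1$ means drug $j$ opposes every off-target action of drug
$i$.

Undefined coefficients ($p_i = 0$ or $s_i = 0$) are reported as `NA`, never
coerced to 0, so zero scores arise only from exact coherent/incoherent ties.

Two screens partition the drug pairs:

* **Synergy screen** — pairs with $p_{ij} > 0$ and $s_{ij} = 0$ (purely
  pharmacological overlap); buckets `mutual_high` (both $a \ge 0.5$),
  `unilateral_high`, `positive`, `zero`, `negative`.
* **Side-effect screen** — pairs with $p_{ij} > 0$, $s_{ij} > 0$ and a
  strict coherent majority on the pharmacological overlap
  ($p^{++} + p^{--} > p^{+-}$, i.e. positive synergy; ties excluded);
  buckets `beneficial`, `neutral`, `aggravating` on the sign of $b$, with
  `mutual_high` / `unilateral_high` sub-flags at the 0.5 threshold.

The 0.5 "high" threshold is configurable. The screens are disjoint by
construction ($s_{ij} = 0$ vs $s_{ij} > 0$).

### Worked examples

```{r worked-examples}
score <- function(fx) {
  sc <- side_effect_score(synergistic_score(
    enumerate_shared_pairs(generate_fixture(fx))))
  sc[, c("drug_i", "drug_j", "a_ij", "a_ji", "b_ij", "b_ji")]
}
score("panitumumab_pair")   # single shared pharm target, both -1: a = 1, 1
score("modafinil_pair")     # fully opposed single off-target: b = 1, 1
score("icosapent_pair")     # 8 private off-targets dilute one side: b = 1/9, 1
score("fig6a")              # one mitigated, one aggravated off-target: b = 0, 0
score("amitriptyline_pair") # 4 coherent vs 1 incoherent off-target: b < 0
```

## The synthetic generator

Real signed drug-target data of the published kind is license-restricted, so
the package ships a generator (`generate_network()`) whose defaults emulate
the published network's controlled moments: 1315 drugs, 820 targets, 4128
signed edges with negative fraction 2711/4128 ≈ 0.657, heavy-tailed degree
sequences on both sides, pharmacological flags at rate 2916/11332 ≈ 0.257,
and monochromaticity 0.9 — by default 90% of drugs act with a single sign on
all their targets, reflecting the observation that a drug's signed actions
are almost all of the same sign.

Mechanics and the reasoning behind the genuinely open choices:

* **Degrees.** Drug and target propensities are drawn from a discrete power
  law (default exponent 2.5, a typical value for biological interaction
  networks); edges are sampled proportional to propensity products with
  duplicate rejection. This produces hubs with a single knob; the exponent
  was fixed once and is not fitted to anything.
* **Monochromaticity.** Each drug draws a personal sign (negative with
  probability `negative_fraction`); with probability `m` the drug is
  monochromatic — every signed edge takes the personal sign — otherwise each
  edge draws independently. The drug-level coin (rather than a per-edge
  coin) makes "a drug is monochromatic with probability at least `m`" hold
  exactly for every degree, and leaves the expected negative fraction equal
  to `negative_fraction` either way.
* **Flags.** Pharmacological flags are independent Bernoulli per edge; the
  icosapent-style fixture's private off-targets, whose signs the worked
  example leaves unstated, are set all-negative non-pharmacological — they
  enter the scores only through the count $s_i$, so the choice affects no
  printed value.

What the generator does **not** emulate: target-side sign correlation. In
real data the drugs hitting one target mostly act with one sign, which
pushes the observed coherence probability far above chance (≈ 0.78 against a
null of ≈ 0.55); independent per-drug signs give $\rho \approx q^2 +
(1-q)^2 \approx 0.56$ at $q = 0.657$. Passing tests on generated networks
therefore demonstrate the machinery (enumeration, tests, null preservation,
score algebra), not the real network's coherence excess; the one
qualitative real-data signature the generator does reproduce, at
monochromaticity 1, is the two-tailed coherence histogram with all mass on
the axes. It also makes no attempt at the joint degree-sign distribution or
any target ontology.

## Numerical and degenerate-input choices

* All counts are integers; scores and fractions are single exact divisions
  of integer quantities, so ties are exact and zero buckets contain only
  true ties.
* `binomial_enrichment()` requires $\rho$ strictly inside $(0,1)$ — a
  degenerate $\rho$ means no variation to test against — and `c_ij >= 1`.
* Empty networks are legal everywhere descriptive (summaries, profiles,
  restrictions return empty objects); `coherence_probability()` and
  `cycle_fractions()` on empty input raise errors rather than return
  `NaN`.
* The null model resamples collisions rather than allowing multi-edges, so
  null networks live in the same simple-graph space as the input.
* Identifier spaces of drugs and targets must be disjoint; a string on both
  sides is a hard error protecting bipartiteness.
* Multi-action rows for one (drug, target) pair collapse to one edge:
  agreeing signable labels keep the sign, conflicting ones give sign 0 with
  a `conflicting` flag, and the pharmacological flag is the OR of the rows.
  The collapse rule is this package's choice; source databases do not
  specify one.

## Problem sizes

The bundled analysis scripts and the test suite run the full pipeline at the
published scale (1315 × 820, 4128 edges) including a 100-realization null
ensemble — about half a minute end to end on one core. Property tests
compare the vectorized pair and cycle enumerations against brute-force
oracles on networks up to 25 drugs × 15 targets, hundreds of instances,
which is ample to exercise every code path while keeping the default test
run fast.

## Limitations

Signs are a coarse binarization of mechanism: dose, timing, binding site
and pathway context are all invisible here, and targets whose mode of
action is unclassifiable simply drop out of the signed analysis. The scores
count targets, not effect sizes — a score of 1 on one shared target and on
ten shared targets read very differently. Screens on real extracts inherit
whatever biases the source database's pharmacological-action curation
carries.
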