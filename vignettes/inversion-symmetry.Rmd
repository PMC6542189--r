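---
title: "Inversion symmetry of TF binding at palindromic response elements: models and methods"
author: "palindromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion symmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palindromics)
```

# The element model

Steroid nuclear receptors and several unrelated transcription factors read
palindromic response elements: a half-site of length $n/2$, a short
unconstrained spacer, and the half-site's reverse complement. An
`ElementSchema` captures exactly that — for the 13-nt estrogen response
element the half-site is `GGTCA` with a 3-nt spacer, giving the consensus
`GGTCAnnnTGACC` with $n = 10$ *primary positions* (the spacer carries no
sequence information and is never numbered). Position $p$ and position
$n+1-p$ are reverse complements of each other within the element; we call
them a *palindromic position pair*. The stock schemas are:

```{r schemas}
for (nm in c("ERE13", "HRE13", "ERE15", "HRE15", "p53RE"))
  show(builtinSchema(nm))
```

A *k-nt variant* substitutes exactly $k$ primary positions with non-consensus
bases; there are $\binom{n}{k} 3^k$ of them. For $n = 10$ the 0- through 5-nt
variants number $1 + 30 + 405 + 3{,}240 + 17{,}010 + 61{,}236 = 81{,}922$;
for $n = 12$ the 0- through 6-nt variants total $912{,}718$.

```{r variants}
sum(vapply(0:5, function(k) variantCount(builtinSchema("ERE13"), k),
           numeric(1)))
```

Reverse-complementing a variant maps a substitution at position $p$ with
base $b$ to position $n+1-p$ with the complementary base, so each variant
level is closed under reverse complementation and the consensus is a fixed
point.

# Half-site groups and the vacancy taxonomy

Fixing any $n/2$ primary positions at their consensus identity defines a
*half-site group*: the set of variants whose substitutions avoid the fixed
positions. There are $\binom{10}{5} = 252$ groups for the 13-nt schemas and
$\binom{12}{6} = 924$ for the 15-nt schemas, each containing $4^{n/2}$
elements across levels $0..n/2$.

Each palindromic pair relates to the fixed set in one of three ways: a
**vacancy** (neither member fixed — the pair's consensus identity is absent),
a **double occupant** (both fixed — specified twice), or a **single**. A
counting argument shows vacancies and double occupants always balance, and

$$\sum_v \binom{n/2}{v}\binom{n/2-v}{v} 2^{n/2-2v} = \binom{n}{n/2},$$

which for $n=10$ is $32 + 160 + 60 = 252$ and for $n=12$ is
$64 + 480 + 360 + 20 = 924$. Mapping a group's fixed set through the pair
map yields the group whose members are the reverse complements of its
members. That mapping preserves each pair's occupancy class (the pair
$\{p, n+1-p\}$ meets $F$ and its image in equally many positions), which is
the structural reason the signal-to-noise display is mirror-symmetric:
reverse-complement partner groups carry equal signal. Complementing the
fixed set, by contrast, swaps vacancies with double occupants and negates
the state (below). For $n=12$, groups in which every pair is wholly fixed
or wholly vacant equal their own reverse complement — the 20 *innate
palindromes*, which sit in the centre of the display axis.

The display axis (`axisOrder()`) places the 126 representatives on the left
(sorted by vacancy count, then by the vacancy-pair ranks under an empirical
preference hierarchy, then by double-occupant ranks, then lexicographically
by fixed set) and their reverse complements, reversed, on the right, so
positions $i$ and $\mathrm{total}+1-i$ are always partners. The intra-block
tiebreak beyond the hierarchy is not biologically constrained; any
deterministic choice preserves the mirror pairing, the block boundaries and
the plateau censuses, and we fix the one above for reproducibility.

# The discrete state algebra

A `StateGrouping` partitions the $n/2$ pairs into weighted classes. The
*state* of a group is the weight sum of its vacancy pairs minus the weight
sum of its double-occupant pairs. Because vacancies and doubles balance,
only weight differences matter, and the largest class conventionally
carries weight 0.

Two groupings describe the receptor families: the ketosteroid (4,1)
grouping puts pair 2-9 alone in the weighted class, producing the 3-state
ladder $-X, 0, +X$ with census 56/140/56; the estrogen (3,2) grouping puts
pairs 3-8 and 1-10 in the weighted class, producing the 5-state ladder
$-2X..+2X$ with census 6/60/120/60/6.

```{r states}
sch <- builtinSchema("ERE13")
countDistinctStates(sch, ereStateGrouping(sch))$census
```

With *generic* (algebraically independent) weights, two states coincide
exactly when their per-class vacancy-minus-double coefficient vectors
coincide, so `countDistinctStates()` counts distinct integer vectors — no
floating-point tolerance enters the result. The test suite additionally
confirms every count against a brute-force enumeration using square roots
of distinct primes as weights (distinct sums detected at tolerance
$10^{-9}$, far below the minimal gap between unequal sums at these tiny
integer coefficients). The six partition signatures of five pairs give

```{r ladders}
vapply(list(c(4,1), c(3,2), c(3,1,1), c(2,2,1), c(2,1,1,1), c(1,1,1,1,1)),
       function(s) countDistinctStates(sch, signatureGrouping(sch, s))$nStates,
       numeric(1))
```

Note the (2,2,1) partition: its ladder has 13 rungs
($0, \pm X, \pm Y, \pm(X{+}Y), \pm 2X, \pm(2X{+}Y), \pm(X{-}Y)$ in the two
free weight differences), a count sometimes quoted lower; the
coefficient-vector argument and the generic-weight brute force agree, and
both are exercised in the tests.

# Counting occurrences and the S/N model

`scanElements()` reports every forward-strand window within Hamming
distance $k_{max}$ of the consensus over the primary positions. Only the
sense strand is scanned: a variant and its reverse complement are separate
entries of the element space, and any inversion symmetry in the results
must *emerge* from the data rather than being imposed by double-strand
counting. Windows containing non-ACGT characters at primary *or* spacer
positions are skipped, so every occurrence has an unambiguous location;
this is conservative and affects only assembly gaps and sentinel breaks.
The production scanner is vectorised per offset; the tests hold it equal to
a naive per-window loop on a 100-kb planted genome.

`countInPeaks()` counts an occurrence once for every peak that fully
contains its footprint. Every containment is counted — duplicated elements
inside one peak count each time, overlapping peaks are never merged, and no
least-variant hierarchy is applied (that rule exists separately as
`assignUnique()`, with a deterministic leftmost-then-lexicographic tiebreak
and an audit count of ties). An any-overlap mode and a per-peak presence
mode are available behind flags for sensitivity analysis.

The signal-to-noise ratio compares observed counts with the random-genome
expectation. A specific $n$-position element matches a uniform random
position with probability $4^{-n}$ — once every 1,048,576 nt for $n=10$ —
so a unit aggregating $m$ elements over $N$ peaks of nominal length $L$
expects

$$\lambda = \frac{N \cdot L \cdot m}{4^n}.$$

Two window conventions are provided. The **nominal** convention above uses
$N \cdot L$ and is the default: together with the quantile convention below
it reproduces published significance-threshold pairs exactly. The
**effective** convention replaces $N\cdot L$ with
$\sum_i (L_i - \mathrm{footprint} + 1)$, the exact number of positions at
which an element can be fully contained; it is the correct null expectation
for containment counting and is what the null-calibration tests use. The
two differ by a factor $\approx 1 - (\mathrm{footprint}-1)/L$, immaterial
when the footprint is small relative to the peak length. For variable-width
peak sets, $N \cdot L$ is replaced by the total interval length.

## Poisson significance thresholds

For expectation $\lambda$, `poissonThresholds()` returns
$Q(p)/\lambda$ and $Q(1-p)/\lambda$ where $Q(q)$ is the smallest integer
whose Poisson CDF reaches $q$ (`qpois`). Both one-tailed bounds bracket 1,
depend only on $(\lambda, p)$, and the lower bound is exactly 0 whenever a
zero count is not yet significant ($e^{-\lambda} \ge p$). Reported bounds
are rounded half-up to two decimals (`roundHalfUp()`), the convention of
the published displays; `base::round()`'s round-half-to-even would differ
in the last digit. Under null simulations the empirical exceedance of the
bounds is at or below the nominal $p$ per tail — usually far below, since
the integer quantiles are conservative at small $\lambda$.

## Plateaus

Plateau membership is **structural**: each group is assigned the state
implied by its vacancy/double topology, never clustered from empirical
values — only structural assignment yields exact integer censuses.
`quantifyPlateaus()` then summarises an empirical S/N value per group by
plateau (mean, standard deviation, difference from the zero-state plateau
mean) and estimates the step variables by least squares of the per-group
values on the class coefficients. Both the sample ($n-1$) and population
standard deviations are reported; the sample form is the default
convention. `algebraicChecks()` verifies that fitted plateau means satisfy
the grouping's equation system (for example $AB - CC = Y + Z$ in a
three-class grouping) and reports the maximum residual, which is zero on
noiseless state-linear input and scales with the noise.

# Single-strand k-mer parity

`countKmers()` counts forward-strand k-mers per record, skipping windows
with ambiguity codes; storage is proportional to the distinct observed
k-mers, never $4^k$, so word lengths up to 32 are supported on genome-scale
input. `parityCompare()` relates the count of every k-mer to the count of
its image under reverse complement, reverse, or complement. The default is
zero-inclusive: Pearson correlation, slope and intercept are taken over all
$4^k$ k-mers with absent ones counted as zero, computed analytically from
the observed table (the image counts form a permutation of the originals,
so the moments reduce to sums over observed k-mers and the full vector is
never materialised). Zero-inclusive is the convention under which the
missing-element tallies are meaningful alongside the correlations; a
jointly-present mode is available since the choice is not uniquely
determined. Reverse complementation composes two parity operations
(reverse, complement), so on an exactly mirrored sequence its correlation
is exactly 1 while the single-operation comparisons are unconstrained —
and necessarily equal to each other, as correlation is invariant under
applying the complement permutation to both arguments.

# The synthetic-data generator

The generator exists to give the pipeline inputs with known ground truth.

* `makeGenome()` draws an i.i.d. background from a configurable base
  composition and inserts requested element variants at recorded,
  non-overlapping positions (disjoint footprint blocks), with spacers drawn
  at random. Byte-identical output from a seed.
* `makeMirroredGenome()` emits `S + N + reverseComplement(S)`; the sentinel
  keeps windows from spanning the junction, making reverse-complement
  k-mer parity exact rather than approximate — the reference input for the
  parity engine.
* `makePeaks()` scans for occurrences up to a level cap, emits a peak of
  length $L$ centred on each with probability given by an
  `OccupancyModel`, and adds uniformly placed background peaks. It returns
  its own expected per-element count table (occurrences × occupancy, plus
  the chance of background containment) as recovery ground truth.

The occupancy link is
$P = \mathrm{logit}^{-1}(\alpha - \beta k + \sum_{\text{hit pairs}} w -
\gamma\,[\text{crossover}])$: a baseline $\alpha$, a per-substitution decay
$\beta$ (binding weakens with variant count), a weight per palindromic pair
carrying a substitution (the vacancy-preference hierarchy), and a penalty
$\gamma$ when substitutions occupy both sides of the spacer (crossover
suppression). The logistic form itself is a modelling convenience; the
contract terms the tests rely on are monotone decay in $k$, the pair-weight
hierarchy, the crossover penalty, and invariance under reverse
complementation — which holds because the link depends only on pair
identities and the crossover flag, both preserved by the pair map.

What the generator deliberately does **not** emulate: read-level ChIP noise
and peak calling (peaks are simulated directly), chromatin accessibility,
clustering of binding sites, GC-isochore structure beyond block
composition, and duplicated/repetitive sequence. Passing recovery tests
therefore demonstrate that the *pipeline arithmetic* is faithful — counts,
aggregations, S/N normalisation, plateau fits — not that real cistromes
are free of those complications.

## Study conditions used in the validation suite

The simulation-based checks run at fixed seeds with sizes chosen to make
the tested contrasts decisively resolvable while keeping a full run on one
CPU within a few minutes:

* *Null calibration*: a 2-Mb unplanted uniform genome, 2,000 background
  peaks of 200 nt; the fraction of group×level S/N units outside the
  $p = 0.001$ bounds (effective-window expectation) must not exceed 0.005.
* *Recovery*: a 2-Mb genome planted with 1,000 copies of each 0/1-nt
  variant, occupancy weights $2.0 > 1.2 > 0.7 > 0.35 > 0$ across the pair
  hierarchy, 2,000 background peaks of 50 nt, > 20,000 peaks in total;
  the planted pair ordering must be recovered with Spearman correlation 1
  and the fitted plateau step must sit within three standard errors of the
  same fit on the generator's expected counts.
* *Dim variant*: a sparser 4-Mb genome (150 copies per element) with a
  background-dominated peak universe (12,000 peaks of 146 nt), comparing a
  full model against one with weights scaled to 0.3 and baseline reduced;
  the pair hierarchy is preserved, the low-level amplitude drops, and both
  profiles converge onto $S/N = 1$ at high variant levels. The
  background-dominated design is what makes the noise floor observable: in
  a signal-dominated peak set the windows overlapping planted elements are
  depleted of high-level variants and the floor sits visibly below 1.

# Degenerate inputs and numerical notes

Out-of-range variant levels, non-positive expectations, invalid IUPAC
codes, hierarchies that are not pair permutations, peaks shorter than the
element footprint, odd mirrored-genome lengths and infeasible planting
densities all fail fast with informative errors. Empty peak subsets are
flagged as insufficient rather than scored in the scale-invariance report.
Distinct-state counting is exact integer arithmetic; the only tolerance in
the package's numerics is the $10^{-9}$ rounding guard in the test-side
generic-weight oracle.

# Limitations

* Element matching is exact on A/C/G/T; degenerate-base *schemas* are not
  supported (the IUPAC matcher handles degenerate query patterns over
  concrete peak sequences instead), and spacer length is fixed per schema.
* The S/N expectation assumes a uniform random genome; strongly skewed
  base composition shifts per-element expectations, which is visible in
  simulations with skewed backgrounds and is deliberately not corrected —
  the statistic is defined against the uniform null.
* Whole-genome 20-mer parity tabulation is supported by the engine
  (observed-k-mer storage), but the shipped validation uses synthetic
  genomes of a few megabases.
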