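# palindromics

Inversion-symmetry analysis of transcription-factor binding at palindromic
response elements.

Steroid nuclear receptors (the estrogen receptors and the ketosteroid
receptors AR/GR/MR/PR), and unrelated factors such as p53, bind palindromic
cis-regulatory DNA elements of the form *half-site + spacer +
reverse-complement half-site* — e.g. the 13-nt estrogen response element
`GGTCAnnnTGACC`. Genomes carry not just the consensus but its entire
Hamming neighbourhood: `choose(n, k) * 3^k` elements at each substitution
level *k* over the *n* informative ("primary") positions, 81,922 elements
for *k* = 0..5 at *n* = 10. This package provides the machinery for
analysing ChIP-seq/ChIP-exo binding over that whole neighbourhood, for
computational biologists who want to go beyond position-weight-matrix motif
calls:

* **Element space** — variant enumeration, reverse-complement structure
  (`enumerateVariants()`, `rcElement()`), and the half-site-group taxonomy:
  the `choose(n, n/2)` groups of variants sharing a fixed half of the
  primary positions, classified by which palindromic position pairs
  *p*/*n*+1−*p* are vacancies (neither member fixed) or double occupants
  (both fixed) (`enumerateHalfSiteGroups()`, `axisOrder()`).
* **State algebra** — a weighted partition of the pairs assigns each group
  a discrete state, `state = Σ_vacancies w − Σ_doubles w`; the estrogen
  (3,2) grouping yields the 5-plateau ladder with census 6/60/120/60/6, the
  ketosteroid (4,1) grouping the 3-plateau 56/140/56
  (`stateOfGroup()`, `countDistinctStates()`, `assignPlateaus()`,
  `quantifyPlateaus()`).
* **Occurrence counting and S/N** — forward-strand scanning of genomes for
  variant occurrences, containment counting inside peak sets, and
  signal-to-noise ratios against the random-genome expectation
  `λ = N·L·m/4^n` with one-tailed Poisson significance bounds
  `Q(p)/λ, Q(1−p)/λ` (`scanElements()`, `countInPeaks()`, `snrProfile()`,
  `poissonThresholds()`).
* **Chargaff parity** — single-strand k-mer counting with observed-word
  storage and reverse/complement/reverse-complement population comparisons
  (`countKmers()`, `parityCompare()`).
* **Ground-truth simulation** — seeded genomes with planted variants,
  mirrored genomes with exact reverse-complement parity, and peak sets
  drawn from a logistic occupancy model with a pair-weight hierarchy and a
  spacer-crossover penalty (`makeGenome()`, `makeMirroredGenome()`,
  `makePeaks()`).

## Worked example

Simulate a small cistrome with a planted preference for variants in
palindromic pair 3-8, then recover the signal-to-noise decay by variant
level:

```r
library(palindromics)

sch   <- builtinSchema("ERE13")
g     <- makeGenome(500000, sch, seed = 7,
                    plantings = c(consensus = 120, "3A" = 120,
                                  "8T" = 120, "2C" = 120))
model <- OccupancyModel(alpha = 1, beta = 0.6,
                        pairWeights = c("3-8" = 1.5, "1-10" = 1,
                                        "5-6" = 0.5, "4-7" = 0.25,
                                        "2-9" = 0))
sim    <- makePeaks(g$genome, sch, model, kMax = 2,
                    NBackground = 3000, L = 146, seed = 8)
occ    <- scanElements(g$genome, sch, 2)
counts <- countInPeaks(occ, sim$peaks, elementUniverse(sch, 2))
prof   <- snrProfile(counts, sim$peaks, sch,
                     enumerateHalfSiteGroups(sch),
                     vacancyHierarchy("ERE13"))
round(prof$byLevel[, c("k", "observed", "lambda", "snr", "lower", "upper")], 2)
#>   k observed lambda    snr lower upper
#> 1 0      205   0.49 417.80  0.00  8.15
#> 2 1      598  14.72  40.62  0.27  1.90
#> 3 2      358 198.72   1.80  0.79  1.23
```

The consensus is enormously enriched over the `λ = N·L/4^10 = 0.49`
occurrences expected by chance (S/N ≈ 418), 1-nt variants are ~40-fold
enriched, and 2-nt variants are already close to the noise floor — the
decay-with-*k* profile characteristic of receptor cistromes. The bounds
are the one-tailed Poisson *p* < 0.001 thresholds: values between `lower`
and `upper` are indistinguishable from random occurrence. Per-element
counts show the planted hierarchy directly (`8T` is the reverse complement
of `3A`, and both sit in the favoured pair 3-8):

```r
head(counts[order(-counts$count), c("element_id", "k", "count")], 4)
#>     element_id k count
#> 25          8T 1   217
#> 1    consensus 0   205
#> 8           3A 1   194
#> 6           2C 1   180
```

A command-line wrapper over the same functions ships in
`inst/scripts/palindromics-cli.R` (`enumerate`, `groups`, `scan`, `count`,
`snr`, `plateaus`, `chargaff`, `simulate`).

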