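---
title: "Rank-cutoff optimization for fitness-profile similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-cutoff optimization for fitness-profile similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitrank)
```

## The model

A fitness profile assigns each deletion strain a growth measurement under
one treatment. Platforms disagree about everything except the ordering:
a strain either is or is not among the most impaired. `fitrank` therefore
compares profiles through their rank permutations alone, and asks one
question: *how surprising is the overlap between the informative tops of
the two rankings?*

For cutoffs `i` (query) and `j` (target) over a shared universe of `n`
strains, let `m` be the number of strains in both tops. Under the null
hypothesis that the two rankings are independent, `m` follows the
hypergeometric distribution, and the p-value of an overlap at least as
large is the cumulative tail

$$Hp(m, q, t; n) \;=\; \sum_{x=m}^{\min(q,t)}
  \frac{\binom{q}{x}\binom{n-q}{t-x}}{\binom{n}{t}},
  \qquad q = i,\; t = j.$$

Rather than fixing the cutoffs in advance — there is no universally
correct "top 50" — the optimizer scans every candidate cutoff pair and
returns the pair minimizing $Hp$. The overlap counts for all pairs come
from one pass of the prefix-sum recurrence
$A_{ij} = M_{ij} + A_{i,j-1} + A_{i-1,j} - A_{i-1,j-1}$ over the
permutation match matrix $M$, so the whole scan costs one $O(n^2)$
dynamic program plus one vectorized log-space tail evaluation per grid
cell. At the optimum the package reports the significance
$-\log_{10} p$, the Bonferroni-corrected $\tilde p = N p$ (capped at 1)
for the $N$ grid cells scanned, and the Tanimoto score
$T = m/(q + t - m)$ of the two top sets.

### Assumptions

* Only the **ordering** of strains is meaningful across platforms; raw
  score magnitudes are not compared. Any strictly monotone transform of a
  profile's scores leaves its result unchanged.
* The null model treats the two top sets as uniform random draws from the
  common universe — appropriate when profiles are generated independently,
  and the reason profiles over different strain sets are first intersected
  (`restrict_to_common_strains()`): the tail requires a single well-defined
  population size `n`.
* Deep ranks are assumed to carry noise, not signal; that is what makes
  cutoff selection necessary rather than comparing whole permutations.

## Parameters that matter

* **`k`** (maximal rank cutoff; default `n`). The scan is $O(k^2)$ tail
  evaluations. The default scans the full grid, which is the transparent
  choice and is fast to about `n = 1000` (well under a second here); for
  larger profiles a cap (e.g. `k = 1000`) discards only cutoffs deep in
  the noise region.
* **`polarity`** (per profile; no default detection). Whether a low score
  means a growth defect depends on the scoring scheme (a low p-value and a
  low fold-ratio both do; a z-score may go either way), so it is an
  explicit field rather than a heuristic.
* **`tie_rule`** (default `lexicographic`). The tie-break for equal raw
  scores is not a scientific choice, but it must be deterministic for
  reproducible permutations; lexicographic order by strain id is stable
  across runs and languages. `input_order` is available when the upstream
  file order is itself meaningful.
* **`fixed_query_cutoff`** (binary profiles). A hit list induces ranks
  `1..h` for the hits, but any ordering of the non-hits is arbitrary, so
  optimizing the cutoff over them would be meaningless; the cutoff is
  pinned at `h`.
* **`tier_boundaries`** (tiered genetic profiles). Interaction classes are
  ordered SL > SD > PE by severity, but order *within* a class is
  arbitrary; the only cutoffs whose top sets are well defined are the tier
  ends, so the candidate grid is restricted to them.
* **`n_tests_policy`**. The multiple-testing count `N` is ambiguous in
  principle (per comparison vs per database search). The default counts
  the cutoff pairs evaluated in this comparison, because the correction
  addresses the optimizer's own selection bias; an explicit override
  (`n_tests_policy = "explicit"`) supports database-level correction, and
  repository searches additionally report a per-hit Bonferroni across the
  number of targets, without using it for sorting.
* **Prediction thresholds** (`p_threshold = 1e-10`,
  `tc_threshold = 0.1`, strict inequalities). The stringent operating
  point for calling genetic interactions from profile pairs; both axes are
  needed because extreme significance can coexist with a small absolute
  overlap.

## Numerical choices

* Tails are computed with the log-space hypergeometric survival function,
  carried internally as $\log_{10} p$. The linear `p_value` is also
  reported but underflows to 0 below about 1e-308, which is why
  `significance` is the primary sort key; finite $\log_{10}$ tails were
  verified against an independent log-gamma summation down past
  $10^{-500}$.
* Ties between cutoff pairs with analytically equal p (for instance a cell
  and its transpose with the same overlap) are detected with a $10^{-9}$
  absolute tolerance on $\log_{10} p$ and resolved deterministically:
  smallest $i + j$, then smallest $i$ — the most parsimonious strain sets.
  One consequence: for a tied optimum, swapping query and target returns
  the same *unordered* cutoff pair rather than the mirrored ordered one.
* If no cutoff pair shows any informative overlap (minimum p = 1, e.g. two
  reversed profiles or `n = 1`), the result is returned with significance
  0 and a `no_signal` flag instead of an error.
* A binary-origin fixed cutoff is honored on whichever side of the
  comparison the profile appears (the target side pins `j` exactly as the
  query side pins `i`); restriction to a common universe remaps fixed
  cutoffs and tier boundaries to the count of retained strains at or above
  the original boundary.

## What the synthetic generator emulates

`planted_pair(n, s, noise_swap_rate, seed)` builds two profiles that share
the same `s` strains in their top-`s` ranks, shuffled independently within
the top block and the background, with a fraction of planted strains
swapped out of the target's top. This captures the one feature the method
detects — a common set of genuinely affected strains at the top of both
rankings, with platform noise moving individual strains across the cutoff
— and deliberately nothing else: no dose–response structure, no correlated
barcode-microarray noise, no strain-specific measurement bias. Passing the
planted-recovery tests therefore shows that the optimizer finds a true
shared top through moderate rank noise; it does not certify performance on
real compendia, where noise is structured and overlap is partial in more
complicated ways.

The generator's validation conditions are fixed: recovery uses 200 pairs
at `n = 500` with planted sizes 5–50 and a 5% swap rate; the oracle
equivalence sweep is exhaustive over all permutation pairs up to `n = 5`
(15,016 pairs) plus 500 seeded pairs each at `n` = 6, 7, 8 and 12; the
invariant suite covers 1,000 randomized cases; the scale check runs one
full `n = k = 1000` comparison. These sizes make the full suite complete
in a few minutes while keeping every layer genuinely exercised.

## Design decisions

* **Full-grid default, candidate-set machinery.** The optimizer always
  evaluates an explicit candidate grid; fixed cutoffs and tier boundaries
  are just one-element or few-element candidate sets. This keeps one code
  path for all three profile kinds.
* **The hypergeometric tail is delegated** to R's survival function of the
  hypergeometric distribution (`stats::phyper`), with the package
  contributing the match-accumulation dynamic program, the grid scan and
  the selection rule; tests cross-check the tail against an independent
  direct summation.
* **The profile YAML vocabulary** (11 three-letter keywords, with unknown
  three-letter keys passed through untouched) is a deliberately minimal,
  extensible schema; canonical key order makes writes byte-stable so
  repositories diff cleanly.
* **Flat-file repository.** Profiles are stored as rank-profile YAML
  documents plus a single TSV index — no embedded database — so a
  repository can be rebuilt, inspected and versioned with ordinary tools.

## Known limitations

* The Bonferroni correction addresses the cutoff-pair selection bias but
  is conservative; no permutation null or FDR procedure is provided.
* Strain identifiers are matched verbatim: no ORF-name validation,
  aliasing or synonym resolution. Profiles from platforms with different
  naming conventions must be harmonized upstream.
* Intersecting unequal universes discards strains absent from either
  platform; signal carried by those strains is invisible to the
  comparison.
* The all-vs-all interaction predictor is quadratic in the number of
  genetic profiles; it is meant for repository-scale batches, not for
  millions of pairs.
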