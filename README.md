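# fitrank

Rank-based similarity search for yeast deletion-collection fitness
profiles.

## The problem

Genome-wide fitness screens measure how strongly each strain of a yeast
deletion collection is impaired under a treatment — a compound
(chemical-genetic profiles, homozygous or heterozygous libraries) or a
second gene perturbation (genetic-genetic profiles). Two treatments with a
similar mode of action impair a similar set of strains, so comparing a new
compound's profile against a compendium of public profiles is a direct
route to mode-of-action and drug-target hypotheses. The obstacle is that
published profiles come from different platforms and express fitness in
incompatible ways: fold-ratios, z-scores, p-values, ranks, binary hit
calls, or tiered genetic-interaction classes.

`fitrank` makes such profiles comparable by reducing every scoring scheme
to the one thing they share — the ranking of strains by growth defect — and
then scoring the overlap of the informative tops of two rankings.

## The method

Each profile is converted to a strict rank permutation (rank 1 = most
severe growth defect). For a query and a target over a shared universe of
*n* strains, the overlap count between the top-*i* query strains and
top-*j* target strains for **all** cutoff pairs at once is obtained from
the accumulated match matrix

  A[i,j] = M[i,j] + A[i,j−1] + A[i−1,j] − A[i−1,j−1],

where M is the permutation matrix pairing equal strains across the two
rank axes. Writing m = A[i,j], q = i, t = j, the chance of that overlap is
the cumulative hypergeometric tail

  Hp(m, q, t; n) = Σ<sub>x=m</sub><sup>min(q,t)</sup> C(q,x) C(n−q, t−x) / C(n,t),

and the optimizer returns the cutoff pair (i\*, j\*) minimizing Hp over the
candidate grid (a dynamic-programming scan, evaluated in log space so
p-values down far below 1e−300 keep a finite −log10 p). It reports the
**overlapping significance** −log10 p, a Bonferroni-corrected p̃ = N·p for
the N cutoff pairs scanned, and the **overlapping score**, the Tanimoto
coefficient T = m/(q + t − m) of the two above-cutoff strain sets. Binary
queries pin their cutoff at the hit count; tiered genetic profiles
(severity classes SL > SD > PE) restrict candidate cutoffs to tier ends.

On top of the optimizer sit a three-letter-keyword YAML profile format, a
flat-file profile repository with batch search and two-way
(score × significance) filtering, and an all-vs-all genetic-interaction
predictor (defaults p < 1e−10, T > 0.1).

## A worked example

The canonical 10-strain toy pair has identical top-5 strain sets and
differing deeper ranks:

```r
library(fitrank)
toy <- toy_overlap_pair()
compare_profiles(toy$query, toy$target, optimizer_options(k = 10))
```

```
<overlap_result>
  optimal cutoffs (i*, j*): (5, 5)
  overlap m = 5 of n = 10
  p-value: 0.00397  (Bonferroni x100: 0.397)
  significance (-log10 p): 2.4014
  Tanimoto score: 1.0000
```

All 100 cutoff pairs were scanned; the minimum p = 1/252 ≈ 0.004 is
reached at cutoffs (5, 5), where the two top-5 sets coincide exactly
(m = q = t = 5, hence T = 1). The significance is −log10(1/252) ≈ 2.40.

The same comparison from the shell, plus a repository search:

```sh
inst/cli/fitrank simulate --out fixtures --n 100 --s 20 --seed 4
inst/cli/fitrank import fixtures/target.yaml --repo repo
inst/cli/fitrank search --repo repo --query fixtures/query.tsv
```

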