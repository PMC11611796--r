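# sdweat

Bias assessment for word embedding models: the classic word embedding
association test (WEAT) and a resampling-based dispersion score (SD-WEAT)
with negative-control significance calibration.

## What problem this solves, and for whom

Word embeddings absorb the social stereotypes of their training corpora,
and systems built on them — including clinical and biomedical NLP
pipelines — inherit those associations. Practitioners who need to audit an
embedding model before using it ask two questions: *how strongly* do two
target concepts (say, science vs art terms, or European- vs
African-American names) associate differentially with two attribute
categories (male vs female terms, pleasant vs unpleasant terms), and *is
that association stable* — across the arbitrary split of the attribute
list, across attribute-set sizes, across retrained replicates of the same
model? This package serves that audit: it scores any term→vector mapping
against the ten classic association-test benchmarks (bundled) or your own,
and quantifies both bias and its stability.

## The statistics

For a word vector **w** and attribute sets *A*, *B*, the association is

    s(w, A, B) = mean_{a in A} cos(w, a) − mean_{b in B} cos(w, b)

With targets *X*, *Y*, the effect size (bias score) is the normalized
separation

    d = [ mean_{x in X} s(x,A,B) − mean_{y in Y} s(y,A,B) ]
        / sd_{w in X∪Y} s(w,A,B)

bounded by |d| ≤ 2 for equal-size targets under the population-SD
denominator used here. The one-sided p-value is the fraction of equal-size
partitions (Xi, Yi) of X∪Y whose statistic s(Xi,Yi,A,B) = Σ s(x_i) − Σ
s(y_i) strictly exceeds the observed one (exact enumeration up to 200,000
partitions, Monte-Carlo beyond).

The SD-WEAT removes the dependence on the predefined attribute grouping:
the two attribute sets are pooled, K = 100 new tests are built by drawing
2m random terms from the pool (m = 2 per side by default), and bias is
scored as SD(d₁, …, d₁₀₀). Because the resampled effect sizes are
symmetric around zero, their mean stays near 0 and their *spread* carries
the bias signal. Significance comes from a negative control — the same
procedure with attribute sets drawn from general vocabulary (10,000 tests
in 100 groups of 100) — whose group SDs give μ and σ for
z = (SD_WEAT − μ)/σ and a right-tailed normal p-value.

## Worked example

Everything below is self-contained: the store is synthetic, with a bias
direction of strength β = 1.5 planted between the benchmark's groups.

```r
library(sdweat)

bm <- weat_benchmarks()[["WEAT-7"]]     # math vs arts / male vs female
bm
#> <bias_benchmark> WEAT-7: Math vs arts with male vs female attribute terms
#>   targets  math (8) vs arts (8)
#>   attrs    male (8) vs female (8), pooled 16

store <- generate_synthetic_embeddings(
  synthetic_config(bias_strength = 1.5, seed = 42), bm, n_filler = 500)

run_weat(bm, store, p_mode = "exact")
#> <weat_result> WEAT-7
#>   effect size d = 1.2502, statistic = 0.9672
#>   p = 0.004196 (exact over 12870 partitions/draws)

cal <- negative_control(bm, store, n_tests = 2000, group_size = 100, seed = 7)
cal
#> <null_calibration> WEAT-7: 2000 tests in 20 groups of 100
#>   mu = 0.6879, sigma = 0.0439

sd_weat(bm, store, m = 2, K = 100, seed = 11, calibration = cal)
#> <sdweat_result> WEAT-7: sd_score = 0.8288 (m = 2, K = 100, seed = 11)
#>   mean resampled effect = -0.1519
#>   calibrated z = 3.211, right-tailed p = 0.0006613
```

Reading the numbers: the classic test finds a strong planted association
(d = 1.25 of a maximum 2; only 0.4% of target partitions beat it). The
resampling score (0.83) sits 3.2 control SDs above the random-vocabulary
null level (μ = 0.69), so the pooled attribute terms are far more
polarized with respect to the targets than random words are — the same
conclusion, without relying on the predefined male/female split. The mean
resampled effect (−0.15) is near zero, as the method expects.

To score a real model, point the reader at any word2vec/GloVe text file —
e.g. the public 300-dimensional GloVe release (~2 GB, vocabulary 2.2M) —
and run the full battery:

```r
store <- read_word_vectors("glove.840B.300d.txt")   # glove-text dialect
suite <- run_sdweat_suite(weat_benchmarks(), store, seed = 1)
suite$results          # per-benchmark d, p, sd_score, z, p_right
suite$correlations     # agreement between the two methods
```

The same workflows are available from the shell via the installed
`exec/sdweat` script (`benchmarks`, `simulate`, `weat run`, `sdweat run`,
`stability run` subcommands; every output file carries a manifest header
with the tool version, parameters, seeds and input digests).

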