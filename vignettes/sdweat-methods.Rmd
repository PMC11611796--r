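---
title: "Measuring embedding bias with the WEAT and a resampling-based SD score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring embedding bias with the WEAT and a resampling-based SD score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdweat)
```

## The problem

Word embedding models map terms to real vectors whose geometry reflects the
co-occurrence statistics of the training corpus — including its social
stereotypes. A model in which `nurse` sits closer to female terms and
`doctor` closer to male terms will propagate that association into any
downstream system built on it, which matters wherever such systems support
decisions (health informatics being a prime example). This package
implements two statistics for quantifying such associations from an
embedding alone, plus the machinery needed to validate and compare them:
benchmark term-set handling, vector-file readers, a synthetic planted-bias
generator, significance calibration, and replicate-based stability analysis.

## The classic association test

A benchmark is a tuple of four term sets: targets $X$ and $Y$ (the concepts
under test, e.g. science vs art terms) and attributes $A$ and $B$ (the
categories they may associate with, e.g. male vs female terms). For a word
vector $\vec w$, the association measure is

$$s(w, A, B) = \mathrm{mean}_{a \in A}\cos(\vec w, \vec a) -
              \mathrm{mean}_{b \in B}\cos(\vec w, \vec b),$$

a number in $[-2, 2]$. The effect size is the Cohen's-$d$-style normalized
separation

$$d = \frac{\mathrm{mean}_{x \in X}\, s(x, A, B) -
            \mathrm{mean}_{y \in Y}\, s(y, A, B)}
           {\mathrm{sd}_{w \in X \cup Y}\, s(w, A, B)},$$

and the test statistic is $s(X, Y, A, B) = \sum_{x \in X} s(x, A, B) -
\sum_{y \in Y} s(y, A, B)$. Significance is assessed by a one-sided
permutation test: the p-value is the fraction of equal-size partitions
$(X_i, Y_i)$ of $X \cup Y$ whose statistic strictly exceeds the observed
one. `weat_p_value()` enumerates all $\binom{n}{n/2}$ partitions when that
count is at most `max_exact` (default 200,000 — sub-second at desk scale)
and otherwise draws uniform random partitions (default 10,000).

Two conventions in these formulas are not fixed by the usual notation and
are explicit, documented choices here:

* **Denominator SD.** `weat_effect_size()` uses the population convention
  (divide by $n$) by default. With equal target sizes this gives the
  canonical bound $|d| \le 2$ — the two-point extremal configuration
  ($s$-values split into two constant groups) attains it exactly — and it
  reproduces the published effect sizes of the original test battery on
  public GloVe vectors. The sample convention is available via
  `sd_convention`.
* **Strict exceedance.** The p-value counts strict exceedances only, so
  ties count toward the null. The observed partition is computed with the
  same floating-point expression as the permuted ones, so its structural
  self-tie is exact; a diagnostic warning is raised when more than 1% of
  the *other* partition statistics tie with the observed value, which
  signals a degenerate (e.g. constant) association profile.

## The resampling score

The classic effect size depends on how the attribute list was split into
$A$ and $B$, and on the size of those sets — two choices that are
substantively arbitrary and practically fragile. The resampling score
removes them. For one benchmark:

1. **Pool** the attribute sets into a single list ($A$ then $B$, duplicates
   dropped; `pool_attributes()`).
2. **Resample**: build $K = 100$ new tests, each drawing $2m$ distinct
   terms ($m = 2$ by default) uniformly without replacement from the pool;
   the first $m$ become $A'$, the rest $B'$
   (`resample_attribute_sets()`).
3. **Score**: compute the effect size of each resampled test with the
   original targets, and report the standard deviation of the $K$ effect
   sizes (`sd_weat()`).

The SD is the right summary because the resampled effect sizes are
symmetric around zero by construction — relabeling which half is $A'$
negates each $d_i$ but cannot change their spread — so their *mean* is
expected to be close to zero whether or not the embedding is biased, while
their *dispersion* grows when the pooled attribute terms are genuinely
polarized with respect to the targets. The score lies in $[0, 2]$ given
the effect-size bound. Since it is a dispersion estimate over sampled
replicate tests, the score uses the sample SD ($n - 1$); both it and the
effect-size denominator are switchable for reproduction attempts, and
every result records the conventions used.

Resampled tests are independent draws, so the same $2m$-subset can recur;
with small pools (the minimum is $|{\rm pool}| = 2m$) uniqueness is
impossible and i.i.d. sampling keeps the SD estimator simple.

### Significance: the negative control

A raw dispersion has no scale of its own, so significance comes from a
negative control (`negative_control()`): keep the benchmark's targets,
but draw the resampled attribute sets from general vocabulary instead of
the benchmark's pool — by default 10,000 tests, partitioned in draw order
into 100 groups of 100. The SD of each group yields a control distribution
of dispersion scores with mean $\mu$ and SD $\sigma$, and the benchmark's
score $x$ is standardized as $z = (x - \mu)/\sigma$ with a right-tailed
normal p-value (`sdweat_significance()`). An empirical-quantile variant
(`method = "empirical"`) is provided for sensitivity analysis.

The control depends on the store *and the targets*, so each benchmark gets
its own calibration by default; `share_controls = TRUE` in
`run_sdweat_suite()` lets benchmarks with identical target sets share one
(several of the classic name-based benchmarks form such a family). The
general-vocabulary pool is, by default, a uniform sample of purely
alphabetic terms of length at least two from the first 50,000 vocabulary
entries (file order proxies frequency in standard GloVe releases); both
the filter and the pool size are configurable and recorded.

## Out-of-vocabulary policy

Resolution order in `resolve_terms()` is: exact match; optionally a
lowercased match; for compound terms (spaces or hyphens) that miss as a
whole, the mean of their constituent token vectors — the standard
context-free treatment of compounds. What happens to remaining misses is
the policy: `error` (default for a single classic test, whose meaning
should not silently change), or `lowercase_fallback`/`skip` (default for
resampling runs, which tolerate missing pool words). The pooled attribute
list is resolved once up front, so individual resampled tests cannot fail;
losing more than 20% of the pooled terms — or so many that fewer than
$2m$ remain — aborts the run instead of quietly changing it.

## The synthetic generator

`generate_synthetic_embeddings()` provides the controlled ground truth the
statistics are validated against. Each term's raw vector is

$$v_t = p_t\,\beta\,u + \varepsilon_t,$$

normalized to unit length, where $u$ is a fixed unit axis, $p_t \in \{+1,
-1, 0\}$ is the pole of the term's group (first target and attribute sets
$+1$, second ones $-1$, filler vocabulary $0$), $\beta \ge 0$ is the
planted bias strength and $\varepsilon_t$ has i.i.d. Gaussian components
of scale `noise_scale`. Defaults are dimension 50, $\beta = 1$,
`noise_scale` 1: under these settings effect sizes on the bundled
benchmarks average around 1, the middle of the range reported for real
pretrained vectors, with $\beta = 0$ an exact null and large $\beta$
approaching the theoretical maximum $d = 2$. The generator is fully
deterministic given its configuration, and replicate families
(`generate_replicate_stores()`) share structure while redrawing noise —
the synthetic analogue of retraining a model with a different seed.

What the generator deliberately does *not* emulate: anisotropic vector
geometry, frequency-dependent vector norms and neighborhood structure,
polysemy, multiple correlated bias directions, and the heavy-tailed
similarity distributions of corpus-trained embeddings. Tests passing on
this family therefore validate the statistics' *mathematical* behavior
(bounds, symmetries, null levels, power ordering, stability ordering) —
not any claim about the bias content of real models.

## Stability analysis

`score_replicates()` evaluates each replicate store of one embedding
method on every benchmark with either metric, and
`summarize_stability()` reduces the panel to per-benchmark min/max/SD of
the signed scores (sign flips across replicates are themselves
instability) and ranks methods by the mean of per-benchmark SDs — lower
is more stable. By default each replicate's resampling uses its own
recorded seed, so the spread reflects model variability plus resampling
noise; `freeze_resampling = TRUE` isolates model variability, and is the
mode used when comparing the two metrics' spreads, so that the comparison
is not confounded by resampling noise differences.

## Problem sizes in the bundled validation

The test suite validates on deliberately small instances: exact partition
enumerations up to $\binom{12}{6}$, bound and antisymmetry checks over
10,000 random instances, power curves over 100 generator seeds per bias
level, stability panels of 9 replicates by 10 benchmarks, and calibration
checks over 200 replicate stores with 5,000-test controls (50 groups of
100). The acceptance script scales similarly and derives every random
stream from its `--seed` argument.

## Known limitations

* **The z-calibration is approximate.** The control's $\sigma$ measures
  dispersion-score noise *within* one store and one vocabulary, but the
  benchmark's score also varies with the particular realized attribute
  pool, and with $K = 100$ draws from a pool of a few dozen terms the
  resampled effect sizes are positively dependent, which biases the sample
  SD slightly downward relative to control groups drawn from a larger
  vocabulary. Consequently, under a true null the right-tailed p is only
  approximately uniform: across fresh null stores it is measurably
  overdispersed (the package's own calibration check quantifies this; the
  distributional KS check in the acceptance suite fails its 0.01 bar while
  the companion mean-zero check passes). Interpret borderline p-values
  with this in mind, or use the empirical-quantile variant alongside.
* The exact p-value requires an even pooled target count; after
  out-of-vocabulary losses the implementation still splits the union into
  equal halves and flags unequal target sets rather than aborting.
* Sentence-template expansions of the benchmarks, training of embedding
  models, binary word2vec files, and subword-based synthesis of missing
  words are out of scope; contextual encoders are supported only through
  the store contract (any term-to-vector mapping can be wrapped with
  `embedding_store()`).
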