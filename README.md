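# phonorank

Dirichlet order-statistics modelling of phoneme rank-frequency
profiles, with author-comparison statistics.

## What problem this solves

Word frequencies in long texts follow Zipf's law regardless of who
wrote them, so they carry no author signal at the rank-frequency level.
Phoneme frequencies behave differently: their ranked profile
`f₁ ≥ f₂ ≥ … ≥ fₙ` (n = 44 for the conventional English inventory) is
well described by the expected order statistics of a **symmetric
Dirichlet density**

```
D(θ₁,…,θₙ | β) ∝ ∏ₖ θₖ^(β−1) · δ(Σₖ θₖ − 1),      β > 0,
```

and the single fitted concentration β — together with plain
total-variation distances between frequency vectors — clusters texts
by author. phonorank is for quantitative linguists and stylometry
researchers who want that pipeline as tested, reusable code:

* **phonemize** — plain text + a pronunciation lexicon (CMUdict-like
  tab-separated dialect) → phoneme counts and ranked frequencies,
  under token mode ("all words") or type mode ("different words"),
  with a pairwise common-word ablation;
* **model** — expected ranked curves `f̂ᵣ = ⟨θ₍ᵣ₎⟩` by adaptive
  quadrature of the order-statistic moments, closed-form and
  Monte-Carlo oracles, fluctuation diagnostics;
* **fit** — least-squares estimation of β with `SS_err` and `R²`;
* **compare** — rank-aligned (ρ₁) and label-aligned (ρ₀) variational
  distances, per-author cluster gaps (min cross-author minus max
  within-author), cross-mode inequality reports;
* **simulate** — a seeded generator of synthetic Zipfian corpora with
  known author profiles, so every stage is testable end to end without
  external texts.

The package also bundles, as plain-text fixtures, the published
summary tables of a nine-novel reference corpus (three texts each by
Austen, Dickens and Tolkien): corpus sizes, fitted concentrations per
mode, pairwise distances (×10⁵, as printed) and shared-vocabulary
fractions. See `?reference_study`.

## Worked example

```r
library(phonorank)

## Author separation in the bundled reference tables ------------------
betas   <- reference_fits("all_words")$beta     # 0.61 0.63 … 0.79
authors <- reference_authors()
cluster_gaps(betas, authors, "beta_gap")
#>  Austen Dickens Tolkien
#>    0.02    0.02    0.00

rho1_types <- reference_distance_matrix("different_words", lambda = 1)
cluster_gaps(rho1_types, authors, "distance_gap")
#>  Austen Dickens Tolkien
#> 0.00621 0.00701 0.02833
```

The beta gap is (minimum cross-author |βᵢ−βₖ|) − (maximum within-author
|βᵢ−βⱼ|): positive means the author's concentrations form a separated
cluster. Austen and Dickens separate by 0.02; Tolkien's gap is exactly
zero at printed precision. The distance gaps read the same way on the
pairwise type-mode ρ₁ matrix — all three authors separate.

```r
## The model itself ----------------------------------------------------
spec <- dirichlet_spec(n = 44, beta = 0.8)
round(expected_curve(spec)[1:5], 4)
#> [1] 0.1112 0.0840 0.0705 0.0616 0.0550

f_obs <- as.numeric(sample_ordered(spec, draws = 1, seed = 7))
fit_beta(f_obs)
#> Dirichlet fit (n = 44): beta = 0.639, SS_err x 1e7 = 9846, R^2 = 0.9686
```

A single sampled profile is noisy (the model's own rank-1 relative
fluctuation is ≈ 7%), so one draw fits at 0.64 rather than 0.80; over
200 replicates the mean fit is within 0.05 of truth (checked in the
test suite).

```r
## End to end on a synthetic corpus ------------------------------------
sc <- synthetic_corpus_spec(betas = c(ash = 0.6, birch = 0.75),
                            texts_per_author = 2, tokens_per_text = 30000,
                            vocab_size = 5000, seed = 42)
corp <- gen_corpus(sc)
res  <- compare_corpus(corp$texts, corp$lexicon,
                       corp$ground_truth$text_authors)
round(vapply(res$fits$different_words, `[[`, numeric(1), "beta_hat"), 3)
#>   ash_t1   ash_t2 birch_t1 birch_t2
#>    1.066    1.081    0.950    0.932
round(res$z_gaps$different_words$rho0, 4)
#>    ash  birch
#> 0.4433 0.4458
```

Same-author fits agree to ~0.02 while the authors sit apart, and the
distance gaps are strongly positive: the pipeline recovers the planted
author structure. (Type-mode fits sit above the planted 0.6/0.75
because a shared neutral vocabulary block flattens type-mode profiles;
the vignette discusses this and the generator's other deliberate
departures from real corpora.)

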