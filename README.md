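# soundmeaning

Can you guess what a foreign word means from its sound alone? If
form–meaning mappings in language were fully arbitrary, you could not.
`soundmeaning` is an R package for quantifying and testing cross-linguistic
**form–meaning regularity**: it measures how much closer, in phonetic form,
same-meaning translations are across unrelated languages than
opposite-meaning (antonym) translations, and models whether listeners in a
two-alternative forced-choice antonym task identify foreign word meanings
better than the 50% chance level.

It is aimed at psycholinguists and quantitative linguists working with
IPA-transcribed multilingual stimulus sets and trial-level forced-choice
data.

## What it computes

**Sound-class phonetic distance.** IPA transcriptions are tokenized
(diacritics and tie-bar affricates attach to their base; stress is
stripped) and mapped to coarse sound classes under a shipped, versioned
SCA-style model. Two class strings are compared by global alignment with a
linear gap penalty, and the distance is normalized as

    d(a, b) = 1 − 2·S(a,b) / (S(a,a) + S(b,b)),   clipped to [0, 1],

so identical forms score 0 and unalignable forms approach 1.

**Form–meaning regularity.** For each antonym pair in each language, the
score is the mean (over the pair's two words) of

    R = mean d(word, opposite-meaning translations)
      − mean d(word, same-meaning translations)

computed against the languages outside the target's own language group
(shared ancestry control); positive `R` means same-meaning forms are
closer. A linear mixed model (random intercepts for antonym pair and
language pair) and a within-language concept-label permutation test ask
whether same-meaning distances are systematically shorter.

**Forced-choice accuracy.** Known-word trials are discarded, participants
more than 1.5 SD below the mean digit span excluded, covariates z-scored
on the analysis rows, and accuracy fit with a binomial logit mixed model
(sum-coded factors; random intercepts for participant and item; a
documented convergence fallback ladder). Follow-ups: Sidak-adjusted tests
against chance, pairwise odds-ratio contrasts, and ±1 SD simple slopes.

**Synthetic data.** A generator with a tunable iconicity parameter `rho`
produces lexicons, participants, and logistic-model responses matching the
study design (10 languages in 4 groups, 45 antonym pairs × 3 parts of
speech, 135 trials per participant), so calibration, power and parameter
recovery are all checkable without any download.

## Worked example

```r
library(soundmeaning)

m <- load_sound_class_model()          # shipped "sca_default" table
encode_classes("t͡ʃaː", m)              # "CA"  (affricate + long vowel)
phonetic_distance("kat", "dɔg", m)     # 0.8888889

cfg <- sim_config(n_participants = 30, seed = 3)
lex <- generate_lexicon(cfg)
pp  <- simulate_participants(cfg, lex)
tr  <- simulate_responses(pp, lex, cfg)

rec <- pairwise_distance_table(lex[lex$language != "english", ],
                               scope = "all", model = m)
meaning_effect_test(rec)
#> <meaning effect: estimate -0.00885 (SE 0.00358), chisq(1) = 6.11, p = 0.0134>
permutation_meaning_test(rec, n_perm = 199, seed = 3)
#> <permutation test: observed -0.00885, p = 0.035 (199 shuffles)>
```

The negative estimate says same-meaning translations are about 0.009
distance units closer than opposite-meaning ones across these simulated
languages — a small regularity, of the magnitude the default generator
builds in — and the permutation test agrees it is unlikely under label
exchangeability.

```r
tr  <- standardize_predictors(tr, c("distance_native", "regularity",
                                    "wm_span"))
fit <- fit_accuracy_model(
  tr, correct ~ distance_native_z + regularity_z * wm_span_z, nAGQ = 0)
fit$coefficients
#>   term                   estimate     se      z        p
#> 1 (Intercept)              0.607  0.0357  17.0  8.26e-65
#> 2 distance_native_z       -0.541  0.0390 -13.9  1.00e-43
#> 3 regularity_z             0.204  0.0360   5.66 1.50e- 8
#> 4 wm_span_z                0.121  0.0342   3.55 3.78e- 4
#> 5 regularity_z:wm_span_z   0.0518 0.0350   1.48 1.39e- 1
```

Accuracy sits above chance (intercept 0.61 logits ≈ 65%), falls with
phonetic distance from the native language, and rises with regularity and
digit span; `simple_slopes(fit, "wm_span_z", "regularity_z")` shows the
memory benefit concentrated in high-regularity pairs (OR 1.19 at +1 SD vs
1.07 at −1 SD in this run).

A thin command-line wrapper over the same functions ships at
`inst/cli/soundmeaning` (subcommands `tokenize`, `distance`, `regularity`,
`simulate`, `analyze`, `recover`; every run writes a metadata JSON with
its seed and model version).

## Documentation

The methods vignette (`vignettes/form-meaning-regularity.Rmd`) documents
the distance normalization and its caveats, the regularity score and both
meaning tests, the behavioral model and its convergence ladder, what the
generator does and does not emulate, and the validation experiments with
their problem sizes.
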