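# cdmpath

Learning pathways and learning progressions from cognitive diagnostic
assessment.

## The problem

A total test score says *how much* a student can do, not *what* they can
do. Cognitive diagnostic assessment models a test through a **Q-matrix**
— a binary item-by-attribute table declaring which discrete cognitive
attributes (skills) each item requires — and infers for every examinee a
binary **knowledge state**: which of the K attributes they have
mastered. `cdmpath` implements the complete analysis sequence that turns
dichotomous responses plus a Q-matrix into

1. a **mixed cognitive diagnostic model**: the saturated G-DINA model is
   fitted by marginal maximum likelihood EM, and each multi-attribute
   item is tested with an item-level **Wald test** against five reduced
   families (DINA, DINO, ACDM, LLM, RRUM); admitted families with the
   highest p-value are selected, otherwise the saturated form is kept;
2. **MAP knowledge states**: each examinee is classified into the one of
   the `2^K` states with the highest posterior probability, with
   per-attribute posterior mastery probabilities alongside;
3. a **learning-pathway network**: the most frequent states, stratified
   by number of attributes mastered (Level 0..K), connected by
   first-order transitions (state s → t when s ⊂ t at Hamming distance
   1), with the **dominant learning trajectory** extracted as the
   source-to-sink path carrying the greatest student frequency;
4. a **tiered learning progression**: rare states are absorbed into the
   dominant clusters by nearest-centroid assignment (fixed centers,
   Hamming distance), every examinee is scaled with a **2PL IRT model**
   (EAP under a standard-normal prior), and cluster mean abilities are
   stratified into tiers.

The package is built around a 20-item, 7-attribute high-school English
reading comprehension assessment (attributes A1 difficult vocabulary
through A7 option processing) whose Q-matrix and population summaries
are bundled, and ships a synthetic-cohort generator
(`reading_scenario()`) with a higher-order latent-trait attribute
population, so every stage is testable without confidential exam data.

The core measurement model: responses are conditionally independent
given the state α, `P(x_j = 1 | α)` depends on α only through the
attributes item j requires, and the marginal likelihood is a mixture
over all `2^K` states with free proportions π. For a DINA item
`P = g + (1 − s − g)·∏_{k∈req} α_k`; the saturated G-DINA item gives
every reduced profile its own success probability; ACDM/LLM/RRUM are
additive on the identity/logit/log link.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort of 20,000 examinees:

```sh
Rscript analysis/01_simulate.R     # cohort + true states -> results/cohort/
Rscript analysis/02_fit_select.R   # mixed model, classification, reliability
Rscript analysis/03_pathway.R      # top-17 states, network, dominant path
Rscript analysis/04_progression.R  # 2PL abilities, clusters, 3 tiers
Rscript analysis/05_profiles.R     # per-student diagnostic profiles
```

`03_pathway.R` prints (abridged):

```
Observed 50 unique states; top 17 cover 95.33% of examinees (19065 of 20000);
935 examinees across 33 rare states excluded from the diagram.
First-order transition network: 17 states, 24 edges across levels 0-7
Dominant learning trajectory:
  0000000 -> 0000010 -> 0100010 -> 0100011 -> 0110011 -> 0110111 -> 0111111 -> 1111111
```

i.e. students typically acquire information matching (A6) first, then
complex-sentence processing (A2), option processing (A7), inter-sentence
relationships (A3), inference (A5), rhetorical structure (A4), and
difficult vocabulary (A1) last. `04_progression.R` reports mean 2PL
ability rising strictly along that trajectory,

```
-1.23 < -0.685 < -0.425 < -0.173 < 0.198 < 0.353 < 0.681 < 1.233
```

and stratifies the 17 clusters into three tiers (boundaries θ = −0.555
and 0.67). `05_profiles.R` finds that raw score 13 is held by 610
examinees spread across 36 distinct knowledge states — same score,
different cognitive profile — which is the case for attribute-level
feedback.

In code, the same pipeline is four calls:

```r
library(cdmpath)
sc  <- reading_scenario(N = 20000, seed = 1)
mm  <- build_mixed_model(sc$responses, sc$q, alpha = 0.05)  # fit + Wald selection
cls <- classify(mm$fit, sc$responses)                        # MAP states
top <- top_states(tabulate_states(cls), k = 17)
dominant_path(build_graph(top$retained))
```

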