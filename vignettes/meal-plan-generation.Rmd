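---
title: "Guideline-aligned meal-plan generation with a variational autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guideline-aligned meal-plan generation with a variational autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietvae)
```

## The problem

Personalized diet recommendation asks for a daily sequence of six meals
(breakfast, morning snack, lunch, afternoon snack, dinner, supper) whose
energy matches a user's requirement and whose macronutrient content respects
dietary guidelines, personalized by anthropometrics (weight, height, age,
BMI), activity (PAL) and medical condition (cardiovascular disease, type-2
diabetes, iron deficiency). dietvae implements a generative approach: a
variational autoencoder (VAE) models user profiles in a latent space, a
recurrent decoder emits one meal per slot, guideline-derived loss terms align
training with nutrition policy, and a portion optimizer removes any residual
energy mismatch exactly.

## User profiles and targets

A profile carries weight (kg), height (m), age, sex, BMR (kcal/day), PAL,
BMI, disease flags and a group label (one of ten population groups,
`user_groups()`). The target energy intake follows the factorial approach
with a BMI-dependent adjustment `D` (default 500 kcal):

$$EI = \begin{cases}
BMR \cdot PAL + D & BMI \le 18.5\\
BMR \cdot PAL & 18.5 < BMI < 25\\
BMR \cdot PAL - D & BMI \ge 25
\end{cases}$$

The boundary conditions are deliberately `<= 18.5` and `>= 25`, making the
target a step function of BMI with jumps of exactly $\pm D$.

Macronutrient targets are daily gram ranges obtained from percent-of-energy
guideline ranges via Atwater factors (4 kcal/g protein and carbohydrate,
9 kcal/g fat and SFA). Published guidance gives ranges, not point values, and
the exact percentages are a policy choice; the bundled defaults (protein
10–20 %E, carbohydrate 45–60 %E, fat 20–35 %E, SFA 0–10 %E, with a stricter
7 %E SFA cap for the CVD group and a 40–50 %E carbohydrate range for T2D) are
a versioned, user-overridable YAML (`default_guidelines()`) so that the
policy is auditable and replaceable without touching the loss machinery.

The encoder input is a fixed-order length-10 vector: the seven continuous
fields (weight, height, BMR, age, BMI, target EI, PAL) min–max normalized to
[0, 1] by fixed population bounds (`default_bounds()`), then the three 0/1
disease flags. Bounds are configuration, not data statistics, so encoding is
deterministic and stable across cohorts; the age bound starts at 15 because
the adolescent group is sampled at ages 15–19 even though adult groups span
20–88.

## The generative model

The encoder is a fully connected layer (ReLU, default width 256) followed by
two affine heads producing $\mu$ and $\log\sigma^2$ of a diagonal Gaussian
(default latent dimension 256). Sampling uses the reparameterization trick
$z = \mu + \sigma \odot \varepsilon$, $\varepsilon \sim N(0, I)$, so that
gradients flow through the stochastic draw. With $\varepsilon$ fixed, the
whole forward pass is a pure function of the input and parameters — a
property the tests rely on heavily.

The decoder is a GRU (default 2 layers × 512 units) unrolled over the six
slots. The recurrence feeds the previous *hidden state* back as the next
input: step 1 consumes an affine projection of $z$, and step $t > 1$ consumes
$h(t-1)$. We read the recurrence literally — the alternative (feeding the
predicted meal embedding back) is a different architecture; the projection of
$z$ to the GRU input width is the minimal reconciliation of dimensions, and
the hidden state is initialized at zero.

Three heads sit on the per-step hidden state:

* a single shared meal classifier over the full vocabulary of $M$ meals.
  Slots have disjoint meal pools, so per step the logits of wrong-type meals
  are set to $-\infty$ before the softmax: masked meals receive probability
  exactly zero and exactly zero gradient. Ties in the argmax break toward the
  lowest meal id (deterministic);
* an energy head whose six step outputs sum to the predicted energy
  intake $\hat{EI}$;
* a nutrient head whose step outputs sum to the predicted 4-vector $\hat{n}$
  of macronutrient grams.

The energy/nutrient heads are training-time auxiliaries. At inference, plan
energy and nutrients are computed from the database values of the selected
meals; this is what lets the portion optimizer achieve an exactly zero
caloric difference rather than an approximate one.

## Losses

Training minimizes the sum of four terms (default weights all 1):

* **Meal cross-entropy** $L_{MC} = -\sum_{t=1}^{6} \log p_{t}[y_t]$ against
  ground-truth plans, batch-averaged. True-class probabilities are floored at
  $10^{-12}$ before the log (with a warning) so a pathological mask cannot
  produce $-\infty$.
* **KL divergence** $L_{KLD} = -\tfrac12\sum_j (1 + \log\sigma_j^2 - \mu_j^2
  - \sigma_j^2)$, the closed-form divergence from $N(0, I)$.
* **Energy loss** $L_{EI}$: MSE between predicted and target energy intake.
  Energies enter in normalized units (kcal / 1000). Raw-kcal squared errors
  would be of order $10^5$ and swamp the other terms in an unweighted sum;
  the normalization constant lives in `train_config()` and per-term weights
  remain available, defaulting to 1 to honor the plain four-term sum.
* **Macronutrient penalty** $L_{macro} = \tfrac1N \sum_{i=1}^{N=4}
  (|min_i - \hat n_i| + |max_i - \hat n_i|)$ against the user's gram ranges.
  Inside the target box this is constant (the mean range width) — the loss
  does not prefer any interior point — and it grows linearly with distance
  outside. It is applied to the differentiable nutrient-head output during
  training, not to database sums. Its gradient is a sign pattern; the measure-
  zero kinks at the bounds are irrelevant in practice.

The $N$ in the energy MSE is the batch size; the $N$ in the macronutrient
penalty is the number of targeted nutrients (4). All four terms are batch
means, non-negative, and logged separately per epoch.

Because no automatic differentiation framework is involved, the package
carries its own reverse-mode gradients for the complete computation graph
(encoder, reparameterization, multi-layer GRU, three heads, four losses).
They are validated elementwise against central finite differences
($h = 10^{-5}$, relative tolerance $10^{-4}$) on a 2-profile, 4-meal toy
model in the test suite.

## Training

`train_model()` runs minibatch Adam (defaults: learning rate $10^{-4}$,
batch 64, 500 epochs) with a fixed seed controlling initialization
(uniform fan-in), data order and $\varepsilon$ draws — two runs with the same
seed are bitwise identical. The 80/20 split is by *profile*, not by plan row,
so no user appears on both sides. No early stopping is used; when validation
plans are supplied the parameters with the best validation cross-entropy are
retained additively (the final parameters are returned as well). A non-finite
loss aborts with the offending term named.

## Weekly plans, masking, and the portion optimizer

A weekly plan is seven daily plans decoded from seven independent latent
draws. To enforce variety, meals selected on previous days have their
probability multiplied by a mask strength $\lambda \in [0,1]$ for the rest of
the week. The default $\lambda = 0$ removes them outright, which guarantees
within-week slot uniqueness while the slot pool lasts; published weekly
variability averages near 5 of 7 suggest the original masking was not
absolute, so $\lambda$ exposes the whole spectrum ($\lambda = 1$ disables
masking). When a slot's unused pool empties mid-week — plausible for small
supper pools — the mask for that slot resets rather than failing.

The optimizer then computes the fractional difference
$d = (EI - \hat{EI}) / \hat{EI}$ between the target and the plan energy
(database values) and rescales every portion by $mp' = (1 + d)\,mp$. One
scalar factor per day, applied to all six meals; nutrients scale linearly
with portions by construction. The adjusted energy equals the target up to
floating-point rounding ($<10^{-9}$ relative in the acceptance checks), which
is the mechanism behind a reported caloric difference of 0.00 ± 0.00
regardless of how well the classifier has been trained. An optional per-meal
portion clamp exists conceptually for downstream realism but is off; clamping
would break the exactness property.

## The synthetic study population

The real meal-plan database behind the original study is proprietary, so the
package ships a generator for a synthetic stand-in, treated as first-class,
tested code. It emulates three things:

* **Cohort**: ten groups apportioned by largest remainder from the reference
  composition (85/158/131/103/92/635/706/766/231/93 per 3000 — reproduced
  exactly at $n = 3000$), sexes alternating within groups for an even split,
  heights uniform on 1.60–2.0 m, group-appropriate ages (adolescents 15–19,
  older adults 65–88, otherwise 20–88 against a global printed range of
  20–88 — the adolescent exception follows the tabulated example profiles),
  BMI drawn in group-appropriate ranges and converted to weight (clipped to
  46–180 kg), athletes at PAL ≥ 1.7, and hard constraints only where the
  group name implies them (overweight 25 ≤ BMI < 30, obese BMI ≥ 30). BMR
  uses Mifflin–St Jeor — the original work tabulates BMR without stating its
  formula, so the generator needs one and this is the standard choice. The
  per-group anthropometric distributions beyond the global ranges are not
  published; the defaults here are documented choices, not reproductions.
* **Meal database**: per-slot counts 286/258/255/253/238/59 (1349 meals) with
  calories and macronutrients drawn per slot from zero-truncated normals.
  Truncation at zero raises the mean of a naive parameterization by up to
  ~30 kcal for high-variance slots, so the parent parameters are
  moment-matched such that the *truncated* distribution has the configured
  mean and sd. The truncated-normal family cannot reach a coefficient of
  variation above 1; macronutrient fields whose configured CV exceeds that
  bound (e.g. snack SFA) fall back to truncation at the configured values,
  with an upward mean bias confined to those fields. Nutrients are drawn
  independently (only marginals are published; no covariances), SFA is
  clipped to total fat, and calories can optionally be re-derived as
  $4P + 4C + 9F$ plus noise.
* **Ground-truth plans**: a randomized greedy search splits the target energy
  across slots proportionally to slot mean calories and picks, per slot, the
  best of a random candidate subset; plans within 10% of the target energy
  are accepted, with retries and a best-effort flag otherwise. This is a
  stated heuristic for producing guideline-respecting, EI-correlated labels —
  not a claim about how the original expert plans were built. The correlation
  with the energy target is what makes the labels learnable.

What passing tests on this synthetic population do **not** show: performance
on real food databases (real meals have nutrient covariances, portion
conventions and naming structure the generator does not emulate), nor the
published accuracy percentages, which depend on the proprietary database and
the authors' trained weights.

## Evaluation metrics

* **Caloric difference**: $100\,|EI - \hat{EI}|/EI$ per day, reported as
  mean ± sd.
* **Macronutrient accuracy**: the original metric's formula is not published.
  The default here scores 100 inside the gram range and degrades linearly
  with the relative distance to the nearest bound,
  $100\max(0, 1 - d/\text{bound})$, floored at 0 (a value outside a zero
  bound scores 0). Because this is a design choice, the coarser
  "fraction of days within range" variant is computed alongside so reported
  numbers are auditable.
* **Weekly variability** on the 1–7 scale, in both published granularities:
  distinct daily plans per week, and distinct meals per slot per week. Both
  are permutation-invariant over days.
* **Latent structure**: `export_latent()` writes posterior means ($\mu$, no
  sampling noise) per profile for 2-D embedding by standard tools (t-SNE is
  deliberately outside the package contract); `latent_silhouette()` scores
  group separation as the mean silhouette width, with a permuted-label
  baseline as the null reference.

## Equivalent-meal expansion

Database expansion through an LLM sits behind a provider interface:
`build_equivalence_prompt()` produces the two-stage prompt (role setup
expecting the acknowledgement "FoodAI is ready", then a per-meal query
demanding CSV with the exact 12-column header), `parse_equivalents()`
tolerantly parses CSV responses (code fences stripped, invalid rows dropped,
slot coerced to the queried meal's), and `equivalence_report()` summarizes
per-field mean ± sd differences between matched pairs. Only the offline mock
provider ships (`mock_equivalents()`): Gaussian per-field jitter, truncated
at zero, seed-reproducible, with default scales set near observed LLM
equivalence spreads (protein ≈ 6.7 g, carbohydrates ≈ 12.6 g, fat ≈ 5.2 g,
SFA ≈ 2.7 g). Live API calls are intentionally out of scope; how many
equivalents per meal and what decoding temperature the original used are not
recoverable, so both are plain arguments.

## Numerical choices and degenerate inputs

* Masked logits are $-\infty$, giving exact zeros after the stable softmax
  (row max over finite entries); an empty admissible slot is an error.
* Argmax ties break to the first (lowest-id) meal.
* `optimize_portions()` refuses plans with non-positive energy.
* Meal ids are dense 1..M (R indexing); checkpoints embed a vocabulary hash
  and refuse databases that do not match.
* Profile BMI is validated against weight/height within 0.005; CSV-read
  profiles recompute BMI and keep the file's 2-decimal value as
  `bmi_reported`.

## Desk-scale experiment sizes

The full-scale regime (3000 profiles × 28 plan-days, 1349 meals, 500 epochs,
256/256/2×512 dims) is the package default configuration. The experiments the
test suite and `scripts/acceptance.R` run end-to-end use a desk-scale study
chosen once: 200 profiles, 4 plan-days per profile, 10 meals per slot,
50 epochs, encoder 64 / latent 32 / GRU 2×64. At this scale training loss
drops markedly from epoch 1, hard masking yields 7/7 slot variability, the
optimizer's exactness is unchanged (it is scale-free), and group structure in
the latent means beats a permuted-label silhouette baseline.

## Known limitations

* The macronutrient-accuracy formula is a documented design choice, so
  absolute accuracy percentages are not comparable against reports using an
  unknown formula.
* The synthetic generator matches marginal statistics only; real nutrient
  covariances, recipes and portion conventions are out of scope.
* Plain-R matrix math keeps the implementation dependency-free and exactly
  reproducible, but it is not built for GPU-scale training.
* The portion optimizer targets energy only; macro-aware re-optimization and
  discrete portion sizes are non-goals.
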