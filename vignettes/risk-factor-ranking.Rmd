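---
title: "Ranking clinical risk factors for diabetic retinopathy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking clinical risk factors for diabetic retinopathy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diabetic retinopathy (DR) screening programs need to know which routinely
collected clinical variables — blood pressure, glycemic markers, diabetes
duration, demographics — carry the most information about DR status, so that
risk-factor-based prescreening can prioritize who gets retinal photography.
`retinorank` implements a dual-route ranking procedure for nine such risk
factors against a binary DR label, validates each ranking with five
classifier families, and selects the factor subset that best predicts DR.

The two ranking routes are deliberately different in kind:

1. **Two-sample t-test.** Each factor's values in the DR group are tested
   against the non-DR group; factors are ordered by ascending p-value. This
   is a marginal, model-free criterion.
2. **Retrain-based Shapley values.** For a classifier family, the value of a
   feature subset $S$ is the prediction of a model *refit on exactly the
   columns in $S$*; feature $i$'s attribution for an instance $x$ is

   $$\phi_i(x) = \sum_{S \subseteq F \setminus \{i\}}
     \frac{|S|!\,(|F|-|S|-1)!}{|F|!}
     \left[ f_{S \cup \{i\}}(x_{S \cup \{i\}}) - f_S(x_S) \right],$$

   with $f_\emptyset$ the constant training positive-class rate. Global
   importance is the mean of $|\phi_i|$ over held-out evaluation instances.
   This is the subset-retraining form of the Shapley value, not the
   conditional-expectation masking used by common SHAP libraries: every
   $f_S$ is a genuinely retrained model, so the attribution reflects what
   the family can learn *without* the feature, at the cost of up to $2^d$
   refits.

Each ranking is converted to integer weights ($d - r$ for 1-based rank $r$,
so the top factor of $d=9$ gets 8 and the bottom gets 0), pruned by a greedy
scan, averaged into an ensemble, and the best ranking prefix is used for the
final model.

## The greedy elimination scan

For each classifier family, factors are visited in rank order while
maintaining a cumulative kept set and `prev_AUC = 0`. The candidate score is
the 5-fold stratified cross-validated ROC-AUC of the kept set plus the
current factor. If `prev_AUC >= curr_AUC` the factor is removed and its
weight zeroed; otherwise it joins the kept set. Two readings of the
published loop are possible; we run an **independent scan per family**, with
`prev_AUC` reset for each, because per-family weight vectors (and per-family
ranking tables) only make sense that way. Similarly, "the score for factor
i" is read as the score of the *cumulative set plus i* (forward selection):
comparing lone-factor models against a running `prev_AUC` from unrelated
subsets would make the comparison meaningless.

Within one scan, all candidate AUCs are computed on an identical fold
assignment (a single derived seed). This makes consecutive comparisons
paired: an accepted factor must improve the AUC on the *same* folds, rather
than beat fold-resampling noise. The accepted AUC sequence is therefore
strictly increasing by construction.

The whole procedure is repeated three times (fresh split, fresh SMOTE,
derived seeds `repeat 1..3`), and the final per-factor weight is the plain
mean over the $5 \times 3$ family-by-repeat grid — equal model weights,
since there is no principled reason to privilege one family. The average is
taken over the full grid in one step, which is order-invariant. Repeats are
fully independent runs: a factor removed in one repeat is re-tested in the
others.

## Preprocessing and class imbalance

The cohort is split 80/20 with per-class stratification (each class
contributes `round(n_class * 0.2)` rows to the test partition). All
preprocessing statistics are fitted on training rows only:

* binary factors: mapped to {0,1} by sorted category order, missing cells
  imputed with the training mode (ties toward the smaller code);
* continuous factors: missing cells imputed with the training median
  *first*, then z-score standardized with the training mean and standard
  deviation (imputation before standardization; the alternative order only
  rescales the imputed constant). A zero-variance column gets scale 1 with a
  warning. Min-max scaling is not offered; z-scoring is what "removing the
  effect of the deviation of the variables" requires.

SMOTE then balances the training partition: synthetic minority rows are
drawn as $x + u(x_{nn} - x)$, $u \sim U(0,1)$, between a minority row and
one of its $k = 5$ nearest minority neighbours (Euclidean distance; ties by
row index). Base rows are cycled so per-row synthesis counts differ by at
most one, and classes end exactly balanced. SMOTE is fitted once on the full
training partition before cross-validation — the greedy scan's folds see
synthetic rows in their training *and* validation parts. This mirrors the
published order of operations; it is optimistic relative to fold-wise
oversampling, but since every candidate subset enjoys the same optimism, the
*ranking* decisions it drives are comparable. The held-out test partition is
never oversampled, so all reported metrics reflect the original ~21.5%
prevalence.

The t-test ranking is likewise computed on the SMOTE-balanced training data
(matching the published sequencing). SMOTE'd p-values are anti-conservative
— interpolated rows are not independent observations — and the package never
uses them for significance claims, only for ordering.

## The synthetic cohort generator

The study's pooled four-survey dataset is private, so the generator emulates
its structure: $n = 3990$, nine factors (three binary, six continuous in
natural clinical units, ages truncated at 40, diabetes duration at 0), ~5%
missing cells (MCAR), and a binary label drawn from a logistic model on
standardized factor values,
$P(y=1) = \mathrm{logit}^{-1}(b + \sum_j \beta_j z_j)$, with the intercept
$b$ solved numerically (Monte Carlo + root finding) to hit the 857/3,990
prevalence. The planted effect pattern encodes the qualitative findings the
pipeline should recover: large standardized log-odds (0.7–0.8) for systolic
blood pressure, glycosylated hemoglobin and diabetes duration; moderate
(0.35) for hypertension history, insulin treatment and fasting glucose;
small (0.1) for BMI and gender; exactly 0 for age. Factors are drawn
independently — the real data's covariance (e.g. SBP with hypertension
history) is not modelled, and no attempt is made to match the published
tables' numeric values, which depend on the private data. Passing the
recovery tests therefore shows the *procedure* can recover a planted
ordering at this size and prevalence, not that it reproduces the clinical
study.

## Classifier families and probabilities

KNN ($k=5$, vote share as probability; tie-free deterministic neighbour
selection by row index), a fully grown impurity-based decision tree
(`rpart`, `cp = 0`), an RBF-kernel SVM whose decision scores are calibrated
to probabilities by a logistic link fitted on the training scores,
unpenalized logistic regression, and Gaussian naive Bayes (variance
smoothing $10^{-9} \cdot \max_j \mathrm{var}_j$; binary columns enter as
Gaussians, as in the standard implementation of the Gaussian variant). Hard
predictions for sensitivity/specificity use a fixed 0.5 probability
threshold. AUC is computed by threshold sweeping with tie grouping and is
internally asserted equal to the tie-corrected Mann–Whitney form to 1e-10.

## Numerical and cost choices

* **Shapley evaluation sample**: local values are averaged over at most 200
  held-out instances; global importance stabilizes well before that.
* **Shapley mode**: exact enumeration is auto-selected for $d \le 12$ when
  calling `shapley_attribution()` directly. The *pipeline* default is Monte
  Carlo permutation sampling with 16 orderings per family and repeat:
  across 5 families × 3 repeats the rank aggregate is already stable, and
  the estimator is unbiased with the telescoping-sum property
  ($\sum_i \hat\phi_i = f_F - f_\emptyset$ exactly). Subset models are
  cached and seeded per subset, so exact and Monte Carlo modes share
  identical models.
* **Training-row caps**: subset models for the Shapley value function are
  fitted on a stratified 500-row subsample of the balanced training data,
  and the greedy/prefix cross-validation on a 1,000-row subsample. Rankings
  depend on score *order*, which is preserved at these sizes, while the RBF
  SVM's quadratic fitting cost is not. The final evaluation models are fit
  on the full balanced training partition.
* **Degenerate inputs**: two constant equal groups give $t=0, p=1$; constant
  unequal groups give $p=0$ with a warning; all ranking ties (equal
  p-values, equal importances, equal ensemble weights) break by ascending
  factor name, so every ordering is deterministic.
* **Seeds**: a single run seed; every stochastic stage (cohort, split,
  SMOTE, subsampling, permutations, fold assignment) consumes a seed derived
  from it by hashing a stage label, so stages are independently reproducible
  and two runs with the same configuration are byte-identical on disk.

## Known limitations

* Retrain-based Shapley importances for flexible families (KNN, fully grown
  trees) assign genuinely nonzero importance to noise features — adding any
  column changes the distance metric or the tree — so a null factor lands at
  the bottom of the *ensemble* ranking reliably, but not necessarily of each
  family's ranking in every run.
* SMOTE-before-CV leaks synthetic information across folds (see above); the
  package keeps it as the default for fidelity to the published design. The
  test partition is unaffected.
* No inter-factor correlation in the generator, no multiple-testing
  correction (p-values are used for ordering only), no SMOTE variants, and
  no confidence intervals on the reported metrics.
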