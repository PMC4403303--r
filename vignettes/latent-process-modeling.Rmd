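---
title: "Latent biological processes in repeated-dose toxicogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent biological processes in repeated-dose toxicogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxitopic)
```

## The model

A repeated-dose toxicogenomic study profiles each drug at several dose
levels and durations against concurrent controls. `toxitopic` treats the
resulting fold-change table as a text corpus: each *treatment* (a unique
drug–dose–time combination) is a document, each differentially expressed
gene contributes tokens in proportion to its fold-change magnitude, and a
*latent biological process* is a topic — a probability distribution over
genes that tend to be perturbed together.

The generative model is the author-topic model in its grouped form: every
document has exactly one author, and the author is either the treatment
itself, its drug, or its dose–time pair, depending on the analysis level.
For author $a$ with topic weights $\theta_a \sim \mathrm{Dir}(\alpha)$ and
topics $\phi_k \sim \mathrm{Dir}(\beta)$, each token picks a process
$z \sim \theta_a$ and a gene $w \sim \phi_z$. Inference is collapsed Gibbs
sampling over the token–process assignments with $\theta$ and $\phi$
integrated out:

$$P(z_i = k \mid z_{-i}, w) \propto (n_{ak}^{-i} + \alpha_k)\,
  \frac{n_{kw}^{-i} + \beta}{n_{k}^{-i} + V\beta}.$$

The prior over processes is *asymmetric* and learned: every
`optimize_interval` sweeps after burn-in, $\alpha$ is re-estimated by
Minka's fixed point on the author–process count table,

$$\alpha_k \leftarrow \alpha_k \cdot
  \frac{\sum_a \Psi(n_{ak} + \alpha_k) - A\,\Psi(\alpha_k)}
       {\sum_a \Psi(N_a + \textstyle\sum_j \alpha_j) - A\,\Psi(\sum_j \alpha_j)},$$

iterated until the largest relative change drops below $10^{-6}$ (at most
1000 inner iterations), with each component floored at $10^{-8}$ rather
than allowed to vanish. Letting prevalent processes carry more prior mass
is what makes the fit robust to overshooting the number of processes: an
unused topic's concentration simply collapses toward the floor.

Point estimates are taken from the final state —
$\hat\theta_{ak} = (n_{ak}+\alpha_k)/(N_a+\sum\alpha)$ and, for the
gene side, both a smoothed estimate
$\hat\phi_{kw} = (n_{kw}+\beta)/(n_k+V\beta)$ used wherever strictly
positive probabilities are required, and a raw estimate $n_{kw}/n_k$ whose
exact zeros give each process a small, readable gene support. Setting
`average_last` averages the estimates over thinned final samples, and
`n_chains` runs independent restarts and keeps the chain with the best
final joint log-likelihood; both are useful because a single Gibbs sample
carries appreciable Monte-Carlo noise and, on unlucky initializations, a
chain can settle in a mode where two rare processes merge — the joint
log-likelihood separates such modes cleanly.

## From intensities to tokens

Fold changes are computed per treatment as the ratio of mean treated to
mean control intensity, with controls matched on (drug, time) and pooled.
Down-regulation is stored reciprocally signed ($-k$ means $k$-fold down)
so the differential-expression cutoff acts symmetrically on magnitude.
The cutoff itself is strict: only $|\mathrm{FC}| > 1.5$ survives; all
other entries become exactly zero. Token counts are
$\mathrm{round}(\mathrm{scale}\cdot|\mathrm{FC}|)$ with half-to-even
rounding and `scale = 1` by default; treatments left with no tokens (a
real possibility at low dose and short duration) are dropped with a
warning rather than an error. An optional signed-token mode emits separate
`_up`/`_dn` vocabulary entries when the direction of regulation should be
kept distinct.

Replicate aggregation uses the arithmetic mean by default (geometric
available), and the regrouping step only reassigns document authorship —
token mass is conserved exactly, which the tests assert.

## Choosing the number of processes

`select_num_topics()` runs seeded k-fold cross-validation over a grid of
K and recommends the perplexity minimizer, breaking ties toward smaller K.
Held-out documents are scored by folding them into the frozen model:
their $\theta$ is inferred by Gibbs sampling with $\phi$ fixed, and
perplexity is $\exp(-\sum \log \sum_k \theta_{dk}\phi_{kw} / N)$.

Two scoring protocols are provided, and the distinction matters. Plain
fold-in infers $\theta$ from the whole held-out document and then scores
those same tokens; it is the right tool for the closed-form sanity checks
(uniform $\phi$ scores exactly $V$; a perfect model scores 1), but because
every scored token also informed $\theta$, extra topics always help and
perplexity decreases monotonically in K — model selection under it
recommends the largest K offered, regardless of corpus size. The
*document completion* protocol therefore splits each held-out document's
tokens in half, infers $\theta$ from one half and scores only the other;
`select_num_topics()` uses it, and with it the planted K is recovered
reliably in the package's simulation tests.

On a corpus at the scale of a full toxicogenomics database the
cross-validated choice lands in the hundreds (the package defaults
document K = 200 at treatment level and K = 100 at drug and dose–time
level as the reference configuration); the vignette-scale simulations use
K of 5–20 so the full procedure runs in seconds.

## Similarity and reduction of animal use

Features (treatments, drugs, or dose–time pairs) are compared through the
symmetric Kullback–Leibler divergence of their process distributions,
$\mathrm{sKL}(p,q) = \sum_k p_k\ln(p_k/q_k) + q_k\ln(q_k/p_k)$, reported
in nats. The divergence is computed on the smoothed $\theta$, which the
prior keeps strictly positive, so all scores are finite; note that
published scores of this kind depend on the logarithm base, which is why
the base is fixed and documented here. Low sKL means similar process
usage; `rank_similar()` returns ascending lists with ties broken by
feature ID.

The reduction analysis asks whether dose or time can be dropped from a
design without disturbing pairwise similarity structure. All unordered
pairs of a drug's treatments (66 for a full 3×4 design) form a regression
design with the unordered dose pair (six levels, Low-Low through
High-High) as a categorical predictor and the absolute day difference as
a continuous one. Three Gaussian-identity GLMs — dose + time, dose only,
time only — are compared by adjusted R², AIC and BIC. The printed model
equations carry no explicit intercept, so dose-containing variants use
full dummy coding of the six-level factor (which spans the intercept) and
the time-only variant keeps an explicit intercept to avoid forcing
sKL = 0 at equal time-points. Adjusted R² is computed against the centred
total sum of squares with the absorbed intercept excluded from the
parameter count; a Gamma-log family is available for the positivity of
sKL, reporting a deviance pseudo-R² labelled as such. A scope is judged
"time reducible" only when the dose-only model wins under *all three*
criteria.

That all-three rule deserves a caveat: for a drug whose process usage is
genuinely time-flat, the time term in the full model is a single spurious
regressor, and the adjusted-R² comparison between the nested models is
exactly an F > 1 rule — which a spurious term passes about a third of the
time by chance. The verdict therefore has roughly two-thirds sensitivity
per dataset even under perfect inference; it is a conservative screen, not
a test with controlled error rates, and repeated designs or seeds should
be inspected before acting on it.

Because gene-level annotation services are external, the package exports
per-process gene lists (one ID per line, with a manifest) for upload, and
offers a local alternative: hypergeometric upper-tail enrichment of a
gene list against user-supplied GMT collections with Benjamini–Hochberg
correction, defaulting the universe to the corpus vocabulary size. These
p-values are a plain Fisher-style overlap test and are not expected to
match any particular service's modified scores.

## The synthetic study generator

`simulate_tg_study()` emulates the statistical structure the analysis
assumes: a drugs × 3-dose × 4-duration factorial with per-time concurrent
controls, log-normal baseline intensities, planted gene modules whose
log2 fold change follows a dose profile and a time profile (flat or
increasing; effects additive on the log scale so the 1.5 cutoff has
predictable penetration), and multiplicative log-normal replicate noise
(sd 0.15 log2 units, 3 replicates per group by default). Module genes at
activated conditions pass the DEG filter; off-module genes pass only
through noise, at under 5% at the default settings.

What it deliberately does not emulate: probe-level artifacts, saturation,
batch effects, correlated noise across genes, or the long-tailed module
size distribution of real pathway biology. Passing tests on these
simulations therefore demonstrates that the inference machinery recovers
the structure the model assumes when that structure is present — not that
real microarray data satisfy those assumptions.

`simulate_att_corpus()` samples directly from the author-topic generative
model and backs the recovery tests; `align_topics()` resolves label
switching by minimum summed total-variation assignment (exhaustive for
K ≤ 8, greedy otherwise, the method recorded in its output).

## Numerical choices and problem sizes

All randomness flows through R's RNG, so a seed makes preprocessing,
training and evaluation bit-reproducible; multi-chain training derives
chain seeds deterministically from the root seed. Sampling uses the seeded
generator for tie-breaks; ranked reports break ties lexicographically
(similar features), by smaller index (topics), or by gene ID (genes), so
output order is deterministic. Likelihoods are accumulated in the log
domain.

The package's test and reference computations use deliberately small
problem sizes chosen so the whole suite runs in minutes on a single CPU:
recovery corpora of 100 documents × 50 tokens over 200 genes with K = 5,
cross-validation grids of {2, 5, 20}, and two-drug factorial studies of
300 genes. At these sizes the topic-recovery error of a correct sampler
is dominated by estimation noise — with ~400–1000 tokens per process the
posterior-mean estimate sits at a mean total-variation distance of about
0.13–0.15 from the planted topics, a floor set by the data, not the
algorithm (tallying the *true* assignments already leaves ~0.08).

## Known limitations

- One author per document is assumed throughout (each treatment belongs
  to exactly one drug and one dose–time pair); multi-author documents and
  variational inference are out of scope.
- $\beta$ is symmetric and fixed; only the document–topic prior is
  asymmetrized and learned.
- Fold-change discretization loses the distinction between, say, 1.6-fold
  and 2.4-fold (both round to 2 tokens) and treats the cutoff as a hard
  gate; no significance testing enters the DEG call.
- sKL is a premetric, not a metric: the triangle inequality is not
  guaranteed and is not relied upon.
- The reducibility verdict is a conservative screen with the sensitivity
  caveat discussed above.
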