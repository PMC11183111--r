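---
title: "Methods: landform-structured assembly analysis of montane floras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landform-structured assembly analysis of montane floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralith)
```

## The scientific problem

Mountain floras — the complete sets of angiosperm species recorded on
individual mountains — differ strikingly between bedrock-defined landform
categories (karst, karst-granitic, granitic, Danxia, desert). `floralith`
implements the quantitative machinery needed to ask whether landform
predicts the richness, phylogenetic diversity, phylogenetic structure and
species age structure of such floras once climate, geography and tectonic
setting are accounted for. The pipeline is: build a dated species-level
phylogeny from a backbone megatree, compute per-flora metrics, compare
landform groups, and fit landform-only versus full regression models with
spatial diagnostics.

## Tree assembly

Backbone megatrees rarely contain every species in a regional checklist,
so the species-level tree is assembled in three steps.

**Sister-genus grafting.** A genus absent from the backbone is attached as
sister to a designated related genus: a node is created at the midpoint of
the sister clade's stem branch (for a sister clade with stem-node age $s$
and crown age $c$, the attachment age is $(s + c)/2$), and the new
representative tip descends from it with terminal branch length equal to
the attachment age, preserving ultrametricity. Which genus is the sister
is curated input (a two-column table), not something the package infers:
that choice comes from prior phylogenetic knowledge.

**Genus-midpoint species binding.** A species whose genus is present is
bound at the phylogenetic midpoint of that genus: $(s + c)/2$ on the genus
stem for genera with two or more tips, and half the stem-to-tip branch for
monotypic genera. When several species are bound to one genus, nothing in
the data determines their mutual arrangement; `floralith` adopts a
pectinate series at the common midpoint age, with successive attachment
ages separated by $\varepsilon = 10^{-8}$ Myr so nodes stay strictly
ordered without visible age distortion. This convention is deterministic
and therefore reproducible; it does not claim to resolve within-genus
relationships.

**Even-spacing age interpolation.** When only a subset of nodes carries
age constraints, `bladj_smooth()` dates the rest: every chain of $m$
undated nodes between a dated ancestor (age $a$) and its nearest dated
descendant (age $d$) receives ages $a - i\,(a-d)/(m+1)$. Where chains
share undated ancestors, chains are processed in order of decreasing
descendant age and already-dated nodes act as fixed interior points, so
the result is deterministic. Constraint inversions (a dated descendant at
least as old as its dated ancestor) are rejected.

**Species ages.** A species' age is its terminal branch length —
the age of its parent node in the sampled tree. These ages are relative
to the tree at hand: a species whose true closest relative is missing
from the tree inherits a deeper divergence, so ages are best read as
comparable among floras computed on the same tree, not as absolute clade
ages.

## Diversity and structure metrics

For a community $S$ of $k$ species on a dated tree with $n$ tips:

* **PD** (Faith): total branch length of the minimal subtree spanning
  $S$. The spanning subtree is not forced through the root, so singleton
  PD is 0; `include_root = TRUE` switches to the rooted convention. The
  two conventions give identical standardized effect sizes whenever the
  null subtrees span the root with probability one, and the choice is
  recorded in output metadata.
* **MPD**: mean patristic distance over all unordered pairs in $S$
  (deep structure).
* **MNTD**: mean distance from each member to its nearest other member
  (shallow structure).

Standardized effect sizes use the **uniform null**: every $k$-subset of
the tree's tips is equally likely. With null mean $\mu$ and null standard
deviation $\sigma$ of the metric at richness $k$:

$$\mathrm{PDI} = \frac{\mathrm{PD} - \mu_{\mathrm{PD}}}{\sigma_{\mathrm{PD}}},\qquad
\mathrm{NRI} = -\frac{\mathrm{MPD} - \mu_{\mathrm{MPD}}}{\sigma_{\mathrm{MPD}}},\qquad
\mathrm{NTI} = -\frac{\mathrm{MNTD} - \mu_{\mathrm{MNTD}}}{\sigma_{\mathrm{MNTD}}}.$$

Positive NRI/NTI indicates phylogenetic clustering, negative indicates
overdispersion. The tips of the supplied tree define the pool, so the
tree should be pruned to the union of matrix species first — that is
what `run_pipeline()` does.

Three engines compute the null moments:

* `enumerate`: exact, over all $\binom{n}{k}$ subsets (population sd,
  since the full distribution is in hand); refused above a configurable
  cap (default $10^5$ subsets).
* `montecarlo`: seeded uniform draws without replacement (sample sd);
  the default when enumeration is infeasible, with `n_rand = 999`.
* `analytic`: exact means in closed form — for PD via per-edge inclusion
  probabilities $p_e = 1 - [\binom{n-m_e}{k} + \binom{m_e}{k}]/\binom{n}{k}$
  with $m_e$ tips below edge $e$, and for MPD as the mean of all pairwise
  distances (independent of $k$). No closed form is implemented for the
  MNTD mean or for any sd, so the analytic engine delegates sds to Monte
  Carlo.

The engines must agree: enumeration against an independent brute-force
oracle, analytic means against enumeration to $10^{-10}$, and Monte Carlo
against enumeration within its sampling error. When the null sd is 0
(a site holding the whole pool) the SES is recorded as `NA` and such
sites drop out of downstream regressions for that response.

## Age structure

`mdt_stats()` reports the mean divergence time (MDT) of a flora plus the
means of the oldest and youngest age quartiles. Quartile size is
$\lceil 0.25\, n \rceil$ with a minimum of one species: the ceiling rule
guarantees nonempty quartiles at any richness, which matters for small
floras (the convention is otherwise unobservable at richness divisible by
four). Pairwise landform comparisons use two-sided independent-samples t
tests, pooled-variance by default (Welch via `var_equal = FALSE`), with
star bins at p < 0.05, 0.001, 0.0001 and 0.00001.

## Regression stage

Numeric predictors are min-max standardized to [0, 1]; area and species
richness are log-transformed before modeling. Collinear climate columns
are removed by an iterative filter: while any pair has |Pearson r| above
0.95, the member of the worst pair with the larger mean absolute
correlation to everything else is dropped (ties: the later column).

The landform-only and full models are Gaussian identity-link GLMs, with
landform dummy-coded against a Danxia reference (and tectonic against
craton), landform-by-climate interactions expressible in the formula, AIC
stepwise selection (`step_aic()`, marginality respected), and
leave-one-out importance: the drop in deviance explained when a term
group — a factor's dummies together, or an interaction — is removed along
with any higher-order term containing it. Deviance explained,
$100\,(1 - D_{res}/D_{null})$, equals $R^2$ for this family. Because
predictors are correlated, leave-one-out deltas deliberately do not sum
to the total.

**Spatial diagnostics.** Spatial weights are k-nearest-neighbour
(default $k = 8$) by great-circle distance, binary then row-standardized,
ties broken by site order; the construction and $k$ are recorded in the
output metadata since they are conventions, not estimates. Moran's I of
model residuals is reported with its null expectation $-1/(n-1)$ and a
normality-approximation z and p.

**Spatial error model.** Residual autocorrelation is absorbed by
$y = X\beta + u$, $u = \lambda W u + \varepsilon$, fitted by maximum
likelihood: the likelihood is concentrated in $\lambda$ (GLS $\beta$ and
$\sigma^2$ given $\lambda$; $\log|I-\lambda W|$ from the eigenvalues of
$W$, summed over conjugate pairs so the result is real for the
non-symmetric row-standardized $W$), and maximised by bounded scalar
search on $(-0.999, 0.999)$ to tolerance $10^{-6}$. AIC is
$-2\log L + 2(p+2)$, counting $\beta$, $\lambda$ and $\sigma^2$. As a
deviance-explained analogue the model reports the Cox–Snell pseudo
$R^2 = 1 - \exp(-\tfrac{2}{n}(\log L - \log L_0))$ against the
intercept-only model; for Gaussian models this reduces exactly to
ordinary $R^2$ at $\lambda = 0$, which is why it is preferred here over
the Nagelkerke-normalised variant (whose normalising constant is
designed for discrete likelihoods). Residual diagnostics use the
innovations $(I - \hat\lambda W)(y - X\hat\beta)$, the component the
model claims is white.

## The synthetic-data generators

The generators exist so that every stage can be exercised end to end
with known truth; their defaults emulate the design of a five-landform,
140-site survey at a desk-scale pool of 200 species with per-site
richness uniform on 10–50.

* **Trees**: pure-birth (Yule) trees conditioned on tip count —
  adequate null topologies and depths for metric testing.
* **Traits**: Brownian motion, giving the phylogenetic signal that turns
  environmental filtering into phylogenetic clustering.
* **Assemblages**: `neutral` draws sites uniformly (exactly the uniform
  null, so SES statistics must calibrate to mean 0, sd 1); `clustered`
  gives each landform an optimum at an equally spaced quantile of the
  trait distribution — guaranteeing between-landform compositional
  differentiation — and samples without replacement with weights
  $\exp(-\tau\,(x - x_{opt})^2)$, the successive-renormalisation scheme
  of weighted sampling without replacement; `overdispersed` uses a
  deterministic greedy maximin ordering seeded with the most distant
  pair, ties broken lexicographically, so its strong negative NRI is
  reproducible by construction. The default $\tau = 10$ is strong
  filtering relative to a Brownian trait of unit rate on trees of depth
  a few Myr.
* **Covariates and responses**: simultaneous-autoregressive draws
  $x = (I - \lambda W)^{-1}\varepsilon$ and spatial-error responses
  $y = X\beta + (I - \lambda W)^{-1}\varepsilon$, the generating process
  the spatial error model assumes.

What the generators do **not** emulate: real climate fields, the actual
geography and unequal landform sample sizes of any particular survey,
speciation/extinction dynamics through time, taxonomic error, or
abundance structure. Passing tests therefore demonstrate that the
machinery is correct under the stated statistical assumptions, not that
any particular empirical dataset satisfies those assumptions.

## Numerical choices and problem sizes

All randomness flows from explicit integer seeds; identical seeds give
bitwise-identical outputs, and `run_pipeline()` writes a metadata sidecar
(engine, `n_rand`, seed, weights $k$, file checksum) next to every CSV.
Ultrametricity is enforced to $10^{-6}$ Myr; binding epsilon is
$10^{-8}$ Myr; the enumeration cap defaults to $10^5$ subsets; Monte
Carlo defaults to 999 draws. The validation suite works at sizes chosen
to make each property sharply testable at interactive runtimes: 10-tip
trees for engine-agreement checks (where enumeration is exact), a
200-tip pool with 600 neutral sites for null calibration (large enough
that the $\pm 0.1$ calibration band on mean SES is several standard
errors wide), 50-replicate recovery experiments at $n = 200$ sites for
the spatial error model. Stochastic checks are asserted at bounds with
known familywise error: a pointwise 3-standard-error band applied to
hundreds of comparisons would be expected to fail somewhere by chance
alone, so suite-wide agreement checks use the Šidák-corrected bound and
additionally require the mean squared normalized error to sit at 1.

## Known limitations

* The genus-midpoint and pectinate-binding rules are conventions for
  placing species without phylogenetic data; within-genus topology in
  the output is not meaningful.
* Species ages from a partially sampled tree are overestimates of
  within-genus divergence times whenever close relatives are absent.
* The uniform null is the only null model provided; abundance-weighted
  metrics and swap-based nulls are out of scope.
* The spatial error model assumes the supplied weights; it estimates
  $\lambda$, not the neighbourhood structure.
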