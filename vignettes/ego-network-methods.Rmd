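---
title: "Ego-network metrics, homophily indices and the synthetic questionnaire generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ego-network metrics, homophily indices and the synthetic questionnaire generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egosna)
```

## The data model

`egosna` models the ego-network (personal network) survey design used
to study the diffusion of community health worker-delivered injectable
contraceptives (CHWDIC) among women of reproductive age: each early
adopter (ego) names `n_alters` women (default 10), and all ties — both
ego–alter and alter–alter — are reported *by the ego*, as a symmetric
binary "talks about the innovation with" relation. A network therefore
has `n = n_alters + 1` actors and `n(n-1)/2` possible unordered ties.

Two representation choices matter downstream:

* **Ties are stored undirected**, but every reported count uses the
  directed-symmetric convention of classic SNA software, in which each
  unordered pair counts twice: an 11-actor network has 110 possible
  ties, and `directed_tie_count()` is always `2 × |ties|`. This single
  canonical representation reproduces published tie-count columns
  exactly while keeping symmetry an invariant rather than a file-format
  accident. Asymmetric adjacency input is OR-symmetrized with a
  warning: the relation is symmetric by design, so a one-sided report
  still records a tie.
* **The social relationship** (relative, co-worker, neighbour, …) is an
  attribute of the alter relative to her ego, not an edge type; the
  one relation the tie set encodes is communication about the
  innovation. Multiplex or weighted edges are out of scope.

`marriage_type` may be missing only for single actors — the one
structurally-forced missingness pattern in the questionnaire.

## Metrics

All statistics are implemented from their definitions and computed at
full precision; report tables render at 2 decimal places, rounding half
away from zero (`round_half_up()`), the convention of the survey
reports this package emulates.

* **Density** `T/(n(n-1))` with `T` the directed tie count.
* **Degree centrality**: distinct tied actors; **average degree**
  `T/n`, so `average_degree × n = directed_tie_count` identically.
* **Betweenness**: for actor `v`,
  `Σ_{s<t, s,t≠v} σ_st(v)/σ_st` over unordered pairs, geodesics on the
  undirected graph, disconnected pairs contributing 0 (the standard
  convention; nothing in the survey design motivates a penalty).
  Implemented with Brandes' dependency accumulation — one BFS per
  source, the accumulated total halved because each unordered pair is
  seen from both ends. *nBetweenness* divides by the maximum
  `(n-1)(n-2)/2` and multiplies by 100, so a star centre scores 100 and
  every actor of a complete network 0. The test suite keeps an
  independent oracle that counts geodesics through adjacency-matrix
  powers (`σ_st` = number of minimal-length walks) and checks equality
  on hundreds of random graphs with `n ≤ 8`, plus an igraph
  cross-check; the oracle shares no code with the implementation.
* **Freeman degree centralization**
  `Σ_v (C_max − C_v) / ((n-1)(n-2)) × 100`: 0 for regular graphs, 100
  for a star. Undefined (`NA`) below `n = 3`, as is normalized
  betweenness.

## Homophily

The **group E-I index** for one group of a binary partition is
`(E − I)/(E + I)` where `I` counts ties with both endpoints in the
group and `E` ties with exactly one. It is −1 when all ties stay
internal (perfect homophily), +1 when all cross, and undefined — shown
as "–" in report tables — when the group is empty or has no counted
ties. Ties touching an actor whose attribute value is missing are
excluded from both counts; this keeps the partition well-defined and
the index inside [−1, 1] under missingness.

Attributes with more than two levels are compared through a **binary
recoding** declared in the attribute scheme. Education is the
interesting case: collected at three levels (none / primary-or-secondary
/ tertiary) but compared as "less than secondary" vs "at least
secondary". Where the pooled primary-or-secondary level falls is a
genuine coding choice the source tables leave open, so both variants
ship; the default (`pool_primary_up`) places it in "at least secondary"
on the grounds that the pooled level contains secondary completers. No
claim is made that this matches the original analysts' choice, and
`default_scheme("pool_primary_down")` selects the other reading.

The **actor-level homophily classification** behind homophily-source
summaries is this package's declared interpretation (published tables
of this kind rarely state a formula): an actor is homophilic on an
attribute when a strict majority of her counted ties go to actors of
her own recoded category, i.e. her actor-level `E − I < 0`. An actor
with exactly half internal ties is *not* homophilic; isolated actors
and actors with missing values are `NA` and count only in denominators.
The cutoff is a `threshold` argument wherever the rule is applied, so a
more or less permissive rule is one flag away
(`--homophily-rule` on the CLI).

## Sociogram export

`export_sociogram()` writes GraphML (via xml2) or DOT with the survey's
visual key as node *attributes* — shape (circle = injectable
contraceptive user, square = non-user), colour (red ego; pink
relatives/close friends, blue close friends, black co-workers, green
neighbours), size strictly increasing in degree, and a `boxed` flag on
the actors with the top three betweenness values. Rendering and layout
are left to standard GraphML/DOT consumers. Boxing rules: no boxes when
all betweenness values are equal; actors at the network minimum are
never boxed (a star boxes only its centre); a genuine tie at the third
rank boxes all tied actors and logs a message — deterministic and
inclusive where the convention is unstated.

## The synthetic questionnaire generator

The field data behind the design are available only on request, so the
generator is a first-class module that emulates the *study conditions*:
20 egos split 10/10 across two sites, 10 alters each (220 actors),
attribute marginals equal to the published actor composition (62.7%
aged ≥30, 98.2% married, 80.5% Hausa, 84.1% injectable users, …), egos
forced to be married adopters (the design recruits early adopters;
the published ego marginals are 100% on all three), and
`marriage_type` missing for singles. A numeric `age` is drawn uniformly
within the actor's age band (18–29 / 30–45) so per-network age
summaries can be tabulated; it is an extension of the categorical
codebook, not part of it.

Each unordered pair receives a tie independently with probability

```
plogis( qlogis(p0) + Σ_attr w_attr · 1[same category] )
```

Assortativity enters on the log-odds scale so weights compose
additively and probabilities never need clipping; ego–alter and
alter–alter pairs are treated identically. Defaults, chosen once as
plausible study conditions: `p0 = 0.65` and weights
`(ethnicity 1, age_group 0.5, education 0.5, marriage_type 0.25)`,
ordering the weights by the strength of homophily the study observed
(ethnicity strongest, marriage type weakest); realized mean density at
these defaults is ≈0.84, inside the published 0.46–1 range and near its
0.78 mean. Reproducibility: one root seed, with each network's RNG
substream seeded by `root + hash(label)` — adding networks never
perturbs earlier ones, and `generate_study()` is byte-deterministic for
a fixed config.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: attributes are sampled independently (the
published tables give only marginals, so education×occupation and
similar joint structure is absent); tie formation has no dyadic or
triadic dependence (no transitivity, no ERGM terms); and name-generator
elicitation bias (egos listing well-connected contacts first) is not
modelled. Tests against synthetic data validate the *pipeline*, not
sociological conclusions.

## Numerical and design choices

* Rendering rounds half away from zero at 2 dp (1 dp for percentages in
  descriptive tables); all computation is full precision. Three rows of
  the published per-network table print densities inconsistent with
  their own tie counts (50/110 = 0.4545 printed 0.46; 94/110 = 0.8545
  printed 0.86; 88/110 = 0.80 printed 0.98). These look like
  double-rounding/typo errata; `reported_network_stats()` flags them
  (`density_erratum`) and no check asserts them as truth.
* Degenerate inputs: density needs `n ≥ 2`; normalized betweenness and
  centralization need `n ≥ 3` and are `NA` in summary rows below that;
  empty collections produce header-only files and empty tables rather
  than errors.
* Tie-breaks are deterministic everywhere (canonical tie ordering by
  roster position; boxing ties as above), so identical inputs give
  byte-identical outputs.
* Problem sizes in the test suite — 200 random graphs of `n ≤ 8`
  against the betweenness oracle, 200 replicates per setting for
  generator parameter recovery (density monotone in `p0`,
  majority-group E-I monotone decreasing in the ethnicity weight) —
  are the package's chosen balance of statistical resolution and a
  suite that runs in well under a minute.

## Limitations

Directed or valued ties, multiplex relations, longitudinal designs,
statistical inference on metrics (QAP, permutation tests) and
adoption-dynamics simulation are out of scope: the package reproduces
the descriptive structure of an ego-network survey, nothing more. The
whole-network statistics here are computed *within* each ego network;
they say nothing about the (unobserved) wider network the egos sit in.
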