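---
title: "Models and methods behind pollinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pollinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

# The inference problem

A quantitative visitation network records how many times each
flower-visiting bird species was seen at flowers of each plant species:
an $I \times J$ matrix of counts $a_{ij}$ with total $N$. Two questions
drive the analysis this package implements:

1. *What explains the observed interaction frequencies?* Candidate
   generative hypotheses are encoded as probability matrices $p_{ij}$
   over the cells — relative abundance (neutrality), phenological
   overlap, morphological matching, their products, and a uniform null —
   and compared by the multinomial likelihood of the observed matrix.
2. *What explains the network's structure?* Metrics of the observed
   matrix (connectance, weighted nestedness, evenness, specialization,
   dependence asymmetry) are compared with the distribution of the same
   metrics over networks randomized from each probability matrix.

A third, applied question concerns nectar robbers: flowerpiercers pierce
the corolla base and bypass pollination, so a visitation network
overstates the pollination network. A filter removes robber species and
individually annotated illegitimate visits before re-analysis.

# The multinomial observation model

The package treats the $N$ observed visits as one draw from a multinomial
distribution over the $I \times J$ cells:

$$\ln L = \ln N! - \sum_{ij} \ln a_{ij}! + \sum_{ij} a_{ij} \ln p_{ij},$$

computed with log-gamma so that totals of hundreds of visits cannot
overflow. Models are ranked by $AIC = -2\ln L + 2k$. The parameter count
$k$ is a modelling convention, not an estimate: either the number of
species $S = I + J$ charged once per factor entering the probability
matrix (one factor → $S$, two → $2S$, three → $3S$), or simply the number
of factors (1, 2, 3). Both conventions are implemented and reported;
because $\ln L$ differences at realistic $N$ dwarf the parameter
penalties, the winner rarely depends on the convention, and the ranking
is provably invariant when all candidates carry equal factor counts. The
uniform null matrix is charged as one factor — a choice the source
convention leaves open; it is logged in the output and only affects
comparisons between the null and multi-factor models.

A probability of zero where a count is positive makes the likelihood
undefined. Every builder therefore supports *epsilon repair*: any such
cell is set to $10^{-8}$ (chosen to be less probable than any realizable
cell) before renormalization, the affected cells are recorded in the
object and reported with a warning. The repair is generalized from the
morphology matrix, where it originates, to all builders and products,
because a phenology or abundance matrix can also contain structural zeros
under a positive count.

# Probability-matrix builders

**Phenology.** Species-by-month presence tables (0/1) are multiplied,
plant table times transposed bird table, so each cell counts the months
of joint presence; the matrix is normalized to sum to one. Zero overlap
for *every* pair is an error (no analysis is possible), zero overlap for
some pairs is a legitimate forbidden interaction.

**Abundance.** Monthly flower densities (flowers/ha) and monthly capture
rates (captures per 100 net-hours) are multiplied month by month and
summed — the month-aligned product, not the product of study totals. The
source description ("in the same months") is ambiguous on this point;
monthly alignment is the default and the aggregate product is available
behind `monthly = FALSE` for sensitivity analysis. The normalized matrix
is invariant to rescaling either abundance table, so the two levels'
different units are immaterial.

**Morphology.** Each bird's bill range $[b_{lo}, b_{hi}]$ is first
scaled by $1 + \text{tongue fraction}$ (default 1/3) to account for
tongue reach. Against a flower with corolla-length lower limit $f_{lo}$:
reachable ($b_{lo} \ge f_{lo}$) scores 1; unreachable ($b_{hi} < f_{lo}$)
scores 0; partial overlap scores $(b_{hi} - f_{lo})/(b_{hi} - b_{lo})$ —
the unique linear interpolation consistent with the two boundary rules,
which the source states only as "the proportion of overlap". An
alternative interval-intersection-over-union rule is provided as
`rule = "jaccard"` for sensitivity analysis. The flower's upper length
limit is deliberately unused by the default rule (the criterion gates
only on the lower limit); it is retained in the trait table. Wide-flowered
plants (flagged, e.g. *Puya*) score 1 for every bird because the bird's
head, not bill, enters the corolla. Corolla width enters only through
this binary flag: no numeric width threshold is defined, so inventing one
would be false precision.

**Combinations and null.** Joint hypotheses are normalized element-wise
products; combining with the uniform null ($1/IJ$ everywhere) leaves a
matrix unchanged, which the tests assert. Products are associative and
commutative, so "which order the factors multiply in" is not a degree of
freedom.

# Network metrics and the H2' extrema

Connectance, Shannon interaction evenness and dependence asymmetry follow
their textbook definitions (natural logarithms throughout; the evenness
denominator is $\ln(IJ)$ by default with $\ln(\text{links})$ available,
since the convention is not fixed in the source). Weighted NODF sorts
rows and columns by decreasing marginal totals (stable sort, original
order breaking ties) and requires a *strictly* larger total for a pair to
score; tied margins contribute zero, which is why a perfectly uniform
matrix has WNODF 0. Transposition leaves connectance, evenness and WNODF
unchanged and swaps the two asymmetry values (each level's per-link term
changes sign while the levels exchange roles, so the pair swaps without
further negation).

H2' standardizes the two-dimensional entropy $H_2$ between the extreme
entropies attainable by nonnegative matrices with the observed margins:

- $H_{max}$ is attained by the independence product of the margins. The
  iterative-proportional-fitting construction converges exactly to this
  product from any positive start, so the package evaluates it in closed
  form, $H_{max} = H(\text{row margins}) + H(\text{column margins})$,
  rather than iterating.
- $H_{min}$ is a concave minimization over the transportation polytope;
  its optimum is a vertex, and the simple greedy allocation (place
  $\min(\text{row remainder}, \text{column remainder})$ at the largest
  remaining row × column) can stall in a suboptimal vertex — margins
  rows (5,4) × columns (2,4,3) are a counterexample (greedy entropy
  1.2149 vs true minimum 1.0609). The package therefore uses an exact
  branch-and-bound search for small problems ($N \le 16$ and at most
  5 × 5), and for larger matrices a portfolio of three greedy starts
  polished by steepest 2×2-cycle descent: along any cycle through two
  occupied cells entropy is concave, so only the two extreme steps need
  testing. The heuristic matched exhaustive enumeration on 1,500 random
  small-matrix audits; at study scale its residual error only shifts the
  H2' denominator slightly and identically for observed and null
  networks, so ensemble comparisons are unaffected.

Degenerate margins with $H_{max} = H_{min}$ return 0 with a warning;
networks with a single species on one level raise an error for H2'
(undefined) while WNODF falls back to the pairs of the multi-species
level only.

Chao2 completeness uses the bias-corrected estimator
$S_{est} = S_{obs} + \frac{m-1}{m} \frac{Q_1(Q_1-1)}{2(Q_2+1)}$ and
requires at least two sampling units.

# The constrained null generator

Randomized networks are drawn from a probability matrix at the observed
total $N$ under the constraint that every species receives at least one
interaction (a degenerate replicate with an empty species would make most
metrics incomparable). The source algorithm states the constraint but not
the order of operations; the package fixes it as:

1. visit plant rows in random order, drawing one partner per row from the
   row's conditional probabilities;
2. give each still-empty bird column one interaction, drawing the plant
   from the column's conditional probabilities;
3. distribute the remaining $N - \text{used}$ interactions in a single
   multinomial draw over the whole matrix.

The coverage phase (steps 1–2) distorts cell frequencies slightly — each
row is forced one interaction regardless of its total probability — with
the bias vanishing as $N$ grows past $I + J$; for matrices with roughly
balanced margins the coverage draws are themselves proportional to
$p_{ij}$ and the tests verify frequencies within Monte-Carlo error at
$N = 500$. If $N$ is too small for coverage the generator errors rather
than silently under-delivering. Replicates on which a metric fails are
rejected, logged and resampled (the alternative — keeping partial
replicates — would silently change the ensemble size).

Ensembles are summarized by percentile 95% intervals (2.5/97.5
percentiles, R's default type-7 quantiles) rather than a normal
approximation, because the metrics are bounded and their null
distributions skewed. Verdicts use closed intervals: an observed value
exactly on an endpoint counts as *inside*. Calibration is checked in the
acceptance suite: networks drawn from the same generator fall inside the
intervals at about the nominal 95% rate over 200 trials, with only a
lower bound asserted (0.95 minus three binomial standard errors ≈ 0.904)
because percentile intervals over discrete bounded metrics are
conservative and can legitimately over-cover.

All stochastic operations take a single integer seed; the same seed
reproduces the same networks, ensembles and synthetic communities
bit for bit.

# The synthetic-community generator

The generator emulates the data shapes of a pooled multi-year Andean
study so every pipeline stage has a test surface with known ground truth.
Defaults mirror that study's envelope: 27 plants × 17 birds, 15 months
with simultaneous data, 278 observed visits, and about 5/17 of birds
annotated as nectar robbers.

- *Phenology*: contiguous presence windows with wrap-around (a species
  flowering November–February is contiguous across the year boundary).
  Default widths are drawn uniformly from 3–10 months for plants and
  6–15 for birds: flowering seasons are shorter than bird residency in
  montane systems, and several elfin-forest birds are year-round
  residents.
- *Abundance*: species-level log-normal abundances (plants:
  `meanlog = log(200)`, `sdlog = 1.5` flowers/ha; birds:
  `meanlog = log(1.5)`, `sdlog = 0.8` captures/100 net-hours), applied
  inside the presence window with log-normal monthly jitter
  (`sdlog = 0.3`) and exactly zero outside it. The heavy right skew —
  a few mass-flowering plants, one or two dominant hummingbirds —
  reproduces the rank-abundance shape of real visitation data.
- *Traits*: species mean bill lengths uniform on 9–34 mm and corolla
  lengths on 8–45 mm with ±12% intraspecific ranges, which yields both
  forbidden pairs and partial overlaps at realistic rates; 5% of plants
  are wide-flowered.
- *Observation*: a plain multinomial draw from the chosen driver matrix,
  deliberately **without** the every-species-covered constraint — that
  constraint belongs to the null generator, not to nature — so empty
  margins can and do occur and are pruned downstream.
- *Incidence*: each realized interaction is detected on each sampling day
  with probability $1 - (1 - q)^{a_{ij}}$, so commoner interactions are
  seen on more days; never-detected interactions are absent from the
  table, as in real incidence data.

What a green test does and does not establish: the generator produces
seasonal, skewed, trait-structured communities, but its months are
exchangeable (no wet/dry season correlation between species), detection
is independent across days, and there is no spatial or inter-annual
structure. Recovery results therefore certify the inference machinery,
not the field design.

The package's core scientific self-test draws observations from each
single-factor driver (phenology, abundance, morphology) at
$N = 2{,}000$ on a 20 × 15 community and requires AIC to identify the
true driver against all eight candidate models in at least 90 of 100
seeded replicates — it currently recovers essentially all of them — and
requires both parameter-counting conventions to agree on the winner.

# The packaged fixture is synthetic

The deposited interaction matrix this pipeline was designed around is not
redistributable here, so `inst/extdata/unchog_network_synthetic.csv` is a
constructed stand-in, labelled synthetic in its filename and header. It
satisfies every published structural constraint — 27 × 17 species, 278
visits, 74 unique links, the reported most-connected bird and plant
degrees (26/10/4 and 8/7/7), and the robber-filter outcome (five robber
birds plus six illegitimate pairs reduce it to 26 plants × 12 birds,
dropping *Passiflora cumbalensis*) — but individual cell values are
invented. Tests assert only the published constraints. The trait tables
are likewise plausible-but-invented and carry the same label.

# Known limitations

- Observed-metric values beyond connectance are fixture-dependent and not
  comparable to any published figure, because the real matrix and the
  monthly phenology/abundance tables are unpublished.
- The morphology rule ignores corolla curvature, nectar volume and bird
  body mass; the abundance model ignores detectability differences
  between mist-netting and transects.
- H2' minimization is exact only for small matrices; for large ones it is
  a well-audited heuristic (see above).
- The null generator's coverage bias, though small and documented, means
  cell frequencies are not exactly $p_{ij}$ at small $N$.
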