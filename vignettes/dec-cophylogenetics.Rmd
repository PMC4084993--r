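---
title: "Range evolution and cophylogenetics with decophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range evolution and cophylogenetics with decophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decophy)
```

## The model

`decophy` implements the dispersal--extinction--cladogenesis (DEC) model
of geographic range evolution on a dated, ultrametric, strictly
bifurcating phylogeny, and then re-deploys the same machinery for
cophylogenetics by treating the set of host species a parasite uses as
its "range".

**State space.** A range is a subset of the $N$ areas.  The state space
contains the empty range $\emptyset$, all singletons, and every subset
of size at most `max_range_size` that is connected under a user-supplied
adjacency matrix.  States are ordered by size and then lexicographically,
so every run over the same inputs enumerates states identically.

**Anagenesis.** Along branches ranges evolve by a continuous-time Markov
chain with two rates: range expansion $S \to S \cup \{j\}$ at rate
$\sum_{i \in S} d\, m_{ij} A_{ij}$ (dispersal $d$ per source--target
pair per Ma, scaled by an epoch-specific multiplier $m_{ij}$ and gated
by the adjacency $A$), and range contraction $S \to S \setminus \{i\}$
at rate $e$ per occupied area per Ma.  The empty range is absorbing
inside the generator, but is disallowed at tips and at the root: a
lineage we observe cannot have gone globally extinct, and permitting an
empty root would produce degenerate likelihoods.  Transition matrices
$P = e^{Qt}$ are computed by eigendecomposition of the generator, with a
scaling-and-squaring Padé fallback (`Matrix::expm`) whenever the
eigendecomposition fails a reconstruction check at $10^{-9}$; the state
spaces used here have at most a few hundred states, so either path is
exact to roundoff.

**Cladogenesis.** At a speciation event an ancestral range $S$ is
inherited by the Lagrange convention: if $|S| = 1$ both daughters copy
$S$ (sympatric copy); if $|S| \ge 2$ either one daughter receives a
singleton $\{i\} \subset S$ and the other the remainder $S \setminus
\{i\}$ (vicariance, when the remainder is itself a valid state), or one
daughter receives a singleton and the other retains all of $S$
(peripheral isolate).  Left/right assignments count as distinct
scenarios and all scenarios of a given ancestor are weighted equally.
This convention — and the equally weighted sum over non-empty root
ranges — follows the original ML implementation of DEC; we adopt its
defaults because the analyses this package reproduces used that program
as published, without customising either rule.

**Time stratification.** Epochs are defined by a descending vector of
lower age boundaries ending at 0, each with its own dispersal multiplier
matrix; this is how, for example, elevated dispersal among palaeolake
areas during the Pleistocene is expressed.  A branch crossing an epoch
boundary is split at the boundary and the segment matrices are chained
in time order — the only treatment consistent with rates that change at
an absolute age.  With unit multipliers everywhere the stratified
likelihood equals the unstratified one to $10^{-9}$ (this is tested).

**Likelihood and ancestral scenarios.** The likelihood is computed by
Felsenstein pruning with per-node rescaling.  The relative probability
of a cladogenetic scenario at a node is the fraction of the total
likelihood contributed by fixing that node's split to that scenario; an
inside--outside pass computes all of them in one sweep, and per node
they sum to one by construction.  Ties in scenario ranking are broken by
state-space order, so output is deterministic.

**Fitting.** `fit_dec()` maximises the likelihood over $(d, e) \in
[10^{-9}, 10]^2$ with Nelder--Mead on the log-rate scale from five fixed
starting points (optionally jittered reproducibly under a seed).  The
two-parameter surface is smooth and the multistart guards against the
ridge that appears when the data are nearly uninformative about one
rate.  When every tip shares one singleton range both estimates drift to
the lower bound — the expected ML behaviour, reported rather than
treated as an error.

## Consensus across model runs

Analyses of this kind are typically repeated under several model
variants (different maximum range sizes, with and without dispersal
constraints).  `combine_runs()` implements the acceptance rule used to
summarise such runs: within each run the support for an area at a node
is the summed relative probability of the scenarios whose ancestral
range contains it; an area is *accepted* when its mean support across
runs exceeds 0.7 **and** it is the top-ranked area in every run, with a
*moderate* tier at 0.5 under the same agreement condition, and
*equivocal* nodes otherwise.  The across-run mean with a top-rank
agreement condition is our operational reading of "combined relative
probabilities in agreement between runs"; the source analyses did not
define the combination rule to implementable precision, so the rule is
documented here as a package convention and both thresholds are
arguments, not constants.

## The area = host analogy

`encode_hosts_as_areas()` turns a parasite--host--area association table
into DEC inputs: each terminal (one parasite lineage in one area)
receives as its range the set of host species it uses there, capped at
two hosts — the repertoire cap used in the host-matrix analyses this
package mirrors.  Host "adjacency" defaults to complete (any switch
possible); an optional gate restricts switches to hosts that share at
least one area in the table, mirroring geography-constrained dispersal
without inventing a specific matrix.  Under the analogy, reconstructed
scenarios translate to events (`classify_node_events()`,
`classify_branch_events()`):

* vicariance → **cospeciation**;
* sympatric copy on a singleton → **duplication**;
* peripheral isolate → duplication plus a **sharing** record, keeping
  the 1:1 mapping to the event vocabulary while preserving the
  information that one daughter kept the full repertoire;
* a host present at the bottom of a branch but not at its top →
  **host-switch** (recipient = gained host; the reported donor is the
  first retained host in host order — the data cannot identify which
  retained host was the source);
* a host lost along a branch → **lineage loss**.

Gains and losses are set differences between branch ends, so every
gained host appears in exactly one switch and every lost host in
exactly one loss (tested as a conservation property).

`assign_codivergence_levels()` classifies each parasite lineage:
*Species-Species* (a full parasite species on a single host),
*Species-Lineage* (an intraspecific lineage on a single host), and
*Tribe-Lineage* (a lineage on several hosts).  For the last, the focal
tribes are the goodeine tribes carrying either a plurality of the
lineage's hosts or at least two of them; all other hosts — including
any non-goodeid, flagged by the `non-goodeid:<family>` tribe label —
are listed as exceptions.  The two-pronged rule is needed because one
lineage in the packaged table has a single out-of-tribe goodeine host
(an exception) while another legitimately spans two tribes (both
focal).

## Congruence test

`lca_reconcile()` maps each parasite node to the LCA of its
descendants' host tips.  A parasite node *tracks* a host divergence
when both children map strictly below its own image (they then
necessarily fall under distinct children of that image).  The statistic
is the number of **distinct host nodes** tracked, so a host divergence
echoed by several parasite nodes counts once; it equals $n-1$ for
identical trees under the identity mapping and 0 when all parasites
share one host.  The permutation null shuffles the parasite-tip-to-host
assignment as a multiset, preserving host multiplicities.

The full reconciliation machinery of the interactive tools used for
such tests ("jungles") is not reimplemented: it is not published at
implementable detail, and the question being asked — is the parasite
phylogeny independent of the host phylogeny? — is answered by any
statistic sensitive to shared branching structure.  The LCA cospeciation
count is such a statistic at desk scale.

Because the statistic is integer-valued, the plain permutation p-value
$(1 + \#\{T^\ast \ge T\})/(B+1)$ is conservative under ties and its null
distribution is *not* uniform.  The test therefore also returns a mid-p
and a randomized p-value (ties broken by a single uniform draw); the
randomized version is exactly uniform under the null by exchangeability
and is the right quantity for calibration studies, while the plain
p-value remains the inferential default.

## The simulators and what they do (not) emulate

`simulate_host_tree()` grows a Yule tree at rate $\lambda$ until
`n_tips` lineages exist and cuts it one further $\mathrm{Exp}(n\lambda)$
waiting time later, giving the textbook expected root age
$\sum_{k=2}^{n} 1/(k\lambda)$ (verified against 1000 replicates).

`simulate_cophylo()` drops one parasite on the host root lineage.  At a
host speciation each resident parasite cospeciates with probability
$p_c$ and otherwise follows one daughter chosen uniformly
("missing the boat"); along branches it switches host (rate
$\lambda_s$, recipient uniform among other co-extant host lineages),
duplicates (rate $\lambda_d$) or dies (rate $\mu$).  A switch *moves*
the lineage — it is the analogue of anagenetic dispersal, not a
divergence — so switch counts scale linearly in $\lambda_s$ and the
parasite tree's nodes are exactly the cospeciations and duplications.
All events are logged with ages; the log *is* the ground truth that the
recovery tests compare against.  A run in which every parasite dies is
flagged as empty, not an error.

`simulate_dec_history()` runs the anagenetic CTMC by Gillespie
simulation along every branch (epoch-aware: waiting times are redrawn
at epoch boundaries, which is exact by memorylessness) and draws
cladogenetic scenarios uniformly at nodes.  Extinct ($\emptyset$) tips
are flagged; inference conditions on observed extant tips, so they are
pruned before fitting.

None of the simulators emulate: incomplete sampling, measurement error
in tip ranges, host trees with extinction (the host model is pure
birth), within-host population structure, or rate variation across
lineages.  Passing recovery tests therefore demonstrates correctness of
the inference machinery under the model's own assumptions, not
robustness to their violation in real data.

## Numerical choices and problem sizes

* Ultrametricity tolerance: $10^{-6}$ Ma by default (ages are in Ma
  throughout; trees dated in other units work as long as rates are
  interpreted in the same unit).
* Matrix exponentials: eigendecomposition when the reconstruction error
  is below $10^{-9}$, Padé otherwise; negative entries from roundoff
  are clamped to zero and rows renormalised.
* Optimiser: Nelder--Mead, relative tolerance $10^{-8}$ on the
  log-likelihood, box $[10^{-9}, 10]$ enforced by clamping inside the
  objective.
* Validation sizes: the enumeration oracle sweep uses trees of 2--4
  tips over 2--3 areas (exhaustive sums stay below $\sim 10^5$ terms);
  parameter recovery uses 150--200-tip trees over 4 areas with 10--20
  replicates; congruence calibration uses 500 replicates of 16-tip
  trees with 199 permutations.  These sizes make the whole validation
  suite run in a few minutes on one core while leaving the statistical
  checks well-powered.

## A worked example

```{r example, eval = FALSE}
tab <- margotrema_associations()
assign_codivergence_levels(tab)

enc <- encode_hosts_as_areas(tab)
enc$tip_ranges[["Margotrema bravoae Lineage III@D"]]  # "f" "n"

# a complete simulated analysis
res <- run_pipeline(tempfile("demo"), seed = 7, n_hosts = 10)
res$congruence$p_value
```

## Known limitations

* Only the scalar dispersal and extinction rates are estimated;
  per-pair rates, founder-event (jump) cladogenesis and Bayesian DEC
  are out of scope.
* The consensus rule and the congruence statistic are documented
  package conventions standing in for under-specified steps of the
  original interactive workflow; both are parameterised so users can
  tighten or relax them.
* The packaged association table records only published associations;
  analyses relying on additional unpublished records need those records
  supplied by the user.
* Branch events carry an age interval, not an exact age: an anagenetic
  change is only known to have happened somewhere along its branch.
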