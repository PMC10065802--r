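---
title: "Logical modelling of timer gene and posterior terminal patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical modelling of timer gene and posterior terminal patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timernet)
library(dplyr)
```

## The model

The posterior of the *Drosophila* blastoderm is patterned by an interplay
between three "timer" genes expressed in a stereotyped temporal sequence —
*caudal* (*cad*), *Dichaete* (*D*), and *odd-paired* (*opa*) — and the
posterior terminal system, whose zygotic effectors Tailless (Tll) and
Huckebein (Hkb) are activated at the pole by Torso signalling. `timernet`
implements a deliberately minimal, qualitative model of this system: each
of the seven factors is an ordinal logical variable (Tll, Hkb, D, and Opa
take the levels off/weak/strong; Cad, Fkh, and Wg are off/on), space is
four discrete regions — trunk, tail, hindgut, posterior midgut — that
differ only in their hard-coded Tll/Hkb input schedules, and time is four
synchronous update steps (nuclear cycle 13 through early gastrulation).

At `t0`, Cad is on in every region and all other output factors are off.
Each subsequent state is a pure function of the previous one, computed by
factor-specific rules that never change over time:

* **Cad** is on by default (it is maternally deposited, so presence needs
  no activator) and is repressed by any D, by strong Opa, strong Tll, or
  strong Hkb.
* **D** is repressed by any Tll, any Hkb, or strong Opa; absent
  repression it is strong under Cad and weak otherwise (a basal term that
  surfaces only in *cad* mutants, where D activation is reduced rather
  than lost).
* **Opa** climbs one level per timepoint (a ratchet, reflecting its slow
  nuclear-cytoplasmic-ratio-controlled accumulation) unless reset by any
  Tll or strong Hkb. No timer gene feeds back on *opa*: it is an
  input-only component of the timer cascade.
* **Fkh** switches on where Cad coincides with strong terminal input
  (strong Tll or strong Hkb) and is self-maintaining thereafter, so gut
  identity persists after the terminal inputs decay.
* **Wg** requires Fkh and is vetoed by strong Hkb, which separates
  hindgut (Fkh + Wg) from posterior midgut (Fkh only).

The threshold structure carries the model's key distinctions: weak Tll
(tail) is enough to repress *D* and *opa* but not *cad* or *fkh*, which is
precisely what delays the timer sequence in the tail and keeps the tail
from adopting hindgut fate; weak Hkb represses *D* but not *opa*, *cad*,
or *wg*.

Mutants are simulated by clamping the corresponding factor(s) to 0 at
every region and timepoint — clamping is applied after rule and schedule
evaluation, including at `t0`, so a *cad* null never shows the Cad-on
initial condition. `tor-` is the `tll- hkb-` double clamp. The update
semantics are strictly synchronous; regions are fully independent (the
model has no spatial coupling), and nothing in the simulator is random.

```{r}
net <- terminal_network()
net
simulate_genotype(net, "wt") |>
  filter(region == 1, factor %in% c("Cad", "D", "Opa")) |>
  tidyr::pivot_wider(id_cols = factor, names_from = timepoint,
                     values_from = label)
```

## The interaction table

`terminal_interactions()` annotates the 18 pairwise interactions the
rules encode (11 newly inferred timer/terminal interactions and 7 edges
supported by earlier literature), each with sign, presumed directness,
and the minimum source level at which the effect applies. The table is a
reconstruction constrained by those counts and by the genotype phenotypes
the model must reproduce; two edges (Cad->Wg and Tll->Wg) are indirect
net-effect summaries routed through Fkh and deliberately have no term of
their own in the rule table. Each of the other 16 edges is individually
necessary: deleting any one of them (via `terminal_network(exclude =)`)
breaks at least one shipped phenotype expectation, and the test suite
checks exactly that, along with the two documented exceptions.

## The phenotype expectation suite

`expectation_suite()` encodes the qualitative genotype-by-genotype
observations as `r nrow(expectation_suite())` machine-checkable
expectations over five predicate types (point levels, region-wide
absence, strictly-later first switch-off, strictly-lower maximum level,
and exact region-to-region equality of time courses). Conventions worth
noting:

* "Delayed repression" means a strictly later first switch-off time than
  the reference genotype, with expressed-but-never-off ordered after
  every finite timepoint — this covers the *opa* mutant, where trunk D
  decays to weak but persists at the final timepoint.
* "Reduced activation" means a strictly lower maximum level (weak versus
  strong D in the *cad* mutant).
* "Transformed into" means exact equality of level time courses over a
  stated factor subset. For `tll- opa-` region 3 versus the wild-type
  tail the subset is Cad and D, since Opa is clamped and whole-state
  equality is impossible by construction. For the `hkb-`
  midgut-to-hindgut transformation the comparison is within-genotype
  (region 4 versus region 3), which also sidesteps any claim about
  Fkh/Wg onset *timing* in that genotype — with discrete time and the
  shipped schedules the model places hindgut Wg onset at the same
  timepoint in both regions, but only eventual presence is asserted.

```{r}
report <- evaluate_expectations(simulate_genotypes(net))
glance(report)
```

## The sequential-segmentation variant

Sequentially segmenting insects pattern their segments from a posterior
segment addition zone in which cells progress through the same
cad -> D -> opa succession as they leave the zone. `simulate_wavefront()`
runs a rewired timer network on a growing one-dimensional cell row with
a posterior Wnt source to show that such dynamics emerge naturally from
the *Drosophila* cross-regulatory topology once three ancestral-style
features are restored: Cad depends on Wnt (on only where Wnt was present
at the prior step), and *opa* is cross-regulated by the other timer
genes (repressed where Cad is on, D is strong, or Wnt is present).

Two reconstruction choices deserve flagging, since the variant is only
loosely constrained:

* D in the variant is strictly Cad-driven — strong under Cad, decaying
  strong -> weak -> off without it — rather than retaining the basal weak
  term of the blastoderm network. With the basal term, a newborn
  posterior cell would light up Cad, D, and Opa simultaneously on its
  first update and the succession would skip its pure-*cad* phase; with
  strict Cad dependence every cell that resides in the Wnt zone for at
  least two steps traverses cad -> cad+D -> D -> D+opa -> opa in full.
  (Anterior boundary cells of the initial row leave the zone after a
  single step and may skip the cad+D phase; their phase sequence is
  still ordered and revisit-free.)
* Geometry is dimensionless: the default configuration starts with two
  cells, both inside a two-cell Wnt zone, and appends one naive cell per
  step for twenty steps — enough for the anterior cells to complete the
  succession while a steady wavefront trails the growing posterior. No
  mapping to embryonic stages or micrometres is attempted.

Setting `wnt_range = 0` reverts Cad to its intrinsic default-on rule and
the Cad-on initial condition; together with `opa_timer_repression =
FALSE` and zero growth this reduces every cell to the blastoderm trunk
dynamics — a consistency check the tests enforce.

```{r, fig.width = 7, fig.height = 4}
plot_kymograph(simulate_wavefront(wavefront_config()))
```

## Synthetic expression traces

The quantification conventions used for intensity traces along the
anteroposterior axis — windowing to 67.5–97.5% egg length (measured from
the anterior pole), individual min-max normalisation of each gene's
series, and boundary comparison between genotypes — are implemented over
a synthetic trace generator so they can be tested without any imaging
data. A gene's profile is a sum of logistic-shouldered plateau domains
(`baseline + amplitude * logistic((x - anterior)/s) *
logistic((posterior - x)/s)`) plus Gaussian noise floored at zero; the
half-maximum of each shoulder sits exactly at the edge parameter, which
is what makes boundary calls on noise-free traces land on the generating
values and gives the recovery tests a known truth.

Choices made where the conventions underdetermine the code:

* **Boundary operationalisation.** Boundaries are half-maximum (0.5 of
  the normalised range) crossings located by linear interpolation
  between adjacent samples; the threshold is exposed as a parameter
  since reasonable alternatives exist. On noisy traces a shoulder can
  produce several nearby crossings; estimation then takes the first
  rising and last falling crossing of a single-domain trace.
* **Order of operations** is window-then-normalise, matching per-panel
  normalisation of windowed traces; the two orders agree only when the
  extrema lie inside the window, and a test documents the
  non-commutativity.
* **Noise model.** Additive Gaussian noise, seeded explicitly (with a
  fixed default) so every trace is reproducible by construction; the
  generator restores the caller's RNG state.
* The generator emulates smooth multi-domain profiles with additive
  noise only. It does not model optics, nuclear texture, embryo
  curvature, or depth attenuation, so passing recovery tests demonstrate
  correctness of the quantification code, not robustness to real
  confocal artefacts.

Under the conditions the recovery analysis uses — noise at 5% of
amplitude, 301 samples across the axis, edge sharpness of 1% egg
length — at least 95% of 100 seeded runs recover both generating edges
within 0.5% egg length:

```{r}
dom <- domain_spec("cad", 75, 90, amplitude = 10, edge_sharpness = 1)
errs <- unlist(lapply(1:100, function(s) {
  tr <- synthesize_trace(dom, n_points = 301, noise_sd = 0.5, seed = s)
  tr <- normalize_trace(window_trace(tr))
  b <- boundary_positions(tr, "cad")
  c(b$position[b$direction == "rising"][1] - 75,
    tail(b$position[b$direction == "falling"], 1) - 90)
}))
mean(abs(errs) <= 0.5)
```

## Numerical and design notes

* Levels are plain integers; there is no floating point anywhere in the
  simulator, so determinism is exact and reruns are byte-identical.
* Opa resets to 0 (rather than holding its level) when repression
  reappears after it has climbed; under the shipped monotone-decay
  schedules this case never arises.
* The engine is generic over regions, timepoints, factors, and rules
  (`new_network()`), and is checked against an independent brute-force
  recursive evaluation of the rules on both the canonical network and
  randomly generated threshold networks.
* Problem sizes are intrinsic to the model (4 regions x 4 timepoints x 7
  factors; a 22-cell, 20-step default axis; 100-seed recovery runs), so
  the entire test battery completes in well under a minute.

## Limitations

The model is qualitative by design: it has no representation of domain
sizes, expression kinetics, or region growth, so it cannot address the
concerted fate-map shifts seen in some terminal mutants, the graded
retraction of the Tll border, dorsoventral modulation of the D domain,
or cross-regulation of *tll* by Hkb — all deliberately out of scope. The
variant network is a plausibility demonstration, not a fitted model of
any sequentially segmenting species.
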