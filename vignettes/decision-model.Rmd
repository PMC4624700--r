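---
title: "A deterministic decision-tree model of hemostasis strategies after cardiac catheterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic decision-tree model of hemostasis strategies after cardiac catheterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdvalue)
```

## The problem

After a transfemoral cardiac catheterization the arterial puncture must be
closed, either by manual compression (MC, the standard of care) or by a
vascular closure device (VCD). Both can be followed by access-site
complications — hematoma (graded large), retroperitoneal hemorrhage (RPH),
arteriovenous fistula (AVF), pseudoaneurysm (PSA), limb ischemia/arterial
stenosis, and infection — whose inpatient treatment generates costs for the
payer (the German Statutory Health Insurance, SHI). `vcdvalue` implements a
deterministic decision-tree model of this choice and the value-based
pricing analyses built on it: what would a *better* closure device — one
that prevents bleeding complications — be worth to the payer?

## Model structure and assumptions

The tree starts immediately after sheath removal. Its assumptions:

* **Independent complications.** Each of the six complications occurs
  independently with its marginal probability; a patient can contribute
  several. Effectiveness is therefore the *expected number of complications
  per catheterization*, the plain sum of the six rates. Every complication
  counts towards effectiveness, including minor untreated bleeding; only
  costs flow through treatment probabilities.
* **Immediate treatment.** Complications are treated at once (AVF and PSA
  by ultrasound-guided compression, limb ischemia by PTA, infection by
  antibiotics, each with probability 1; large hematomas by transfusion with
  probability 0.2–0.3 %; RPH by two *independent* rules, transfusion and
  endovascular/surgical intervention, 1 % each). Expected complication cost
  is the probability-weighted sum
  $\sum_c r_c \sum_{t \in rules(c)} p_t \, cost_t$.
* **Device failure arm.** The VCD fails with probability 3.6 %, in which
  case manual compression is applied: both effectiveness and cost are the
  two-branch mixture $(1-f)\,E_{device} + f\,E_{MC}$. The fallback itself
  cannot fail (no recursion).
* **24-hour horizon, no discounting**, payer perspective, point estimates
  only — the model is deliberately deterministic (an early-stage
  assessment, not a probabilistic evaluation).

Interventions requiring very large sheaths (TAVI) are outside the model's
scope, as is any quality-of-life weighting of the six endpoints: all
complications count equally.

## Costing

All costs are 2010 German DRG reimbursements (EUR, no adjustment). Because
the base DRG of a catheterization is the same under MC and VCD, strategy
costs differ only through complications:

* Complications absorbed by a *higher-weighted* catheterization DRG
  (transfusion/PTA, US-guided compression) are costed by **difference
  costing**: higher-weighted minus lower-weighted DRG (diagnostic:
  F49A − F49G = 5,299.99; interventional: F24A − F24B = 2,633.40 for
  transfusion/PTA and F19A − F19C = 2,460.18 for US-guided compression).
* Complications with a *distinct* DRG are costed flat: endovascular/
  vascular surgery F08E = 6,834.49, antibiotic treatment T61B = 1,735.05.
* The **combined scenario** blends diagnostic and interventional values
  1:2 (the case mix of the underlying evidence base), entry by entry.

One convention is genuinely open in the source material: the interventional
scenario has *two* base DRGs (F24B for PCI, F19C for other transluminal
cardiac interventions) and no stated rule for combining them. This package
uses their unweighted arithmetic mean as the interventional base
catheterization cost. It is the unique simple rule that reproduces the
published strategy totals in all three scenarios (e.g. MC combined
3,598.96 + 68.35 ≈ 3,667), and it is documented here as a modeling
convention of this implementation.

The AVF rates come from interventional-only evidence but are applied
unchanged in all three scenarios, exactly as the source tables do; blending
them would change the published results.

## Rounding and numerical conventions

Internal computation is always full precision; rounding happens only at
render time — euros to the nearest integer, complication counts to three
decimals, halves away from zero. Dominance classification uses a tie
tolerance of $10^{-12}$ (the model is pure floating-point arithmetic on
fixed inputs). The ICER sign convention puts complications *prevented by
the intervention* in the denominator, so a positive ICER is the price paid
per averted complication.

Two reporting quirks of the published tables are worth knowing:

* The per-complication savings table rounds hematoma savings to €1, but
  the computed value is ≈€0.31 (which is what makes the bleeding total €4
  consistent: 0.31 + 3.78 ≈ 4.1). The package reports the computed value.
* The hypothetical-device ICERs mix conventions: the combined (€547) and
  diagnostic (€780) figures equal the euro-rounded incremental cost divided
  by the 3-dp-rounded effect, while the interventional figure (€604)
  equals the full-precision ratio. `incremental_analysis()` always returns
  the full-precision ICER; the rounded-ratio variant is computed where the
  published convention calls for it.

## The three base analyses

```{r}
tab <- run_all_scenarios()
p <- paper_fixture("combined")
sched <- build_cost_schedule(p$drg_table, "combined")
sav <- savings_by_complication(p$strategies$VCD, sched)
cat(render_report(tab, savings = sav), sep = "\n")
```

In the combined and interventional scenarios the VCD strategy costs more
*and* causes more expected complications than MC — it is dominated, and no
ICER is meaningful. Only in the diagnostic scenario do VCDs prevent
complications (at higher cost), yielding an ICER of €9,142 per averted
complication.

## Hypothetical devices, sweeps, and value-based prices

`make_hypothetical()` scales device-branch rates by factors in [0, 1],
leaving the failure arm untouched — the improved device changes what it
prevents, not what happens when it fails. Because the model is linear in
every rate, per-complication savings are additive and effectiveness sweeps
are exactly linear in the reduction level; both properties are tested
against brute-force enumeration.

Three pricing benchmarks are implemented:

1. **Cost-saving premium** — the complication-cost difference between the
   reference device and the improved device: the largest add-on price at
   which adoption does not raise payer spending (≈€4 for a bleeding-free
   device; €53 if all pseudoaneurysms were prevented instead).
2. **Efficiency-frontier premium** — averted complications valued at the
   ICER of the current standard, usable only where the existing device is
   not dominated (the diagnostic scenario): frontier ICER × complications
   averted ≈ €835 per diagnostic catheterization. This is *gross* of the
   hypothetical device's own incremental complication cost (≈€71 in the
   diagnostic scenario); the net figure is the economically conservative
   bound, and both can be computed from the same objects.
3. **Same-day-discharge savings** — the avoidable ward-cost component of
   the inpatient DRG (resource view, ≈€400) or the inpatient–outpatient
   reimbursement difference (≈€600). These components are not part of the
   DRG table and must be supplied by the user.

## Sensitivity analysis

`one_way_dsa()` varies one probability at a time to the bounds of a
user-supplied range (ceteris paribus) and records the outcome at both
endpoints; `tornado_order()` sorts by spread with a lexicographic
tie-break. Parameters are addressed by path
(`"MC.rates.hematoma"`, `"VCD.treatments.hematoma.transfusion_pta"`,
`"VCD.failure_prob"`), and a substitution in a comparator propagates into
any failure arm that references it — varying an MC rate moves both the MC
strategy and the VCD's failure branch, as it should when they are the same
clinical process.

The confidence limits used in the original tornado analysis are not
reproducible from the published material, so ranges are a required user
input. The bundled
`dsa_ranges_illustrative_synthetic.csv` (point estimates ±30 % relative,
clamped to [0, 1]) is a synthetic stand-in for demonstration only and
carries no evidential weight; with it, the spread ordering illustrates the
machinery, not the published chart. With the `icer` outcome, endpoints at
which the intervention is dominated are flagged rather than computed.

## The synthetic generator

`random_parameters()` draws structurally valid parameterizations — two
strategies with fixture-shaped treatment rules, a failure arm falling back
to the comparator, and a DRG table whose higher-weighted codes dominate
their partners — as a pure function of the seed. Defaults keep instances in
the published regime: rates uniform on [0, 0.2] (all published rates are
below 6 %), costs in [500, 10,000] EUR (the span of the 2010 DRG values),
failure probabilities in [0, 0.1] (published: 3.6 %). Sampling is uniform,
not beta/gamma: the generator serves property testing of a deterministic
model, not probabilistic inference, and it deliberately does *not* emulate
correlations between complications, between rates and costs, or any
real-world case mix — passing property tests says the arithmetic is right,
not that synthetic instances resemble any particular clinical population.

The test suite uses the generator to check the tree engine against a
brute-force enumeration of the full outcome tree (failure branch ×
complication present/absent × each treatment applied/not, expectation by
explicit summation) on 100 random models at $10^{-9}$ tolerance, and the
dominance classifier against a four-quadrant sign oracle. These sizes keep
the whole suite near two minutes on one CPU while exercising every branch
of the engine.

## Interfaces and limitations

Parameterizations round-trip through a single JSON document
(`write_model_config()` / `load_model_config()`); probabilities are stored
as fractions, and input files may declare `"units": "percent"` to have
percentages converted once on load — an explicit flag, to prevent silent
100× errors. DRG tables and DSA ranges read from CSV. A thin command-line
wrapper (`inst/cli/vcdvalue.R`) exposes the analyses as subcommands and
writes a JSON run manifest next to every output.

Known limitations, inherited from the model's design: no severity
weighting or QALYs, no mortality, no probabilistic sensitivity analysis,
no hospital-perspective profitability, no TAVI/large-sheath procedures,
and DRG-based costing that may overstate complication costs where the
highest-weighted DRG is assumed.
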