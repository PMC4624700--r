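# vcdvalue

Deterministic decision-tree cost-effectiveness model of hemostasis
strategies after transfemoral cardiac catheterization, from the payer
(German Statutory Health Insurance) perspective — for health economists and
device developers doing early, desk-scale value assessment.

After catheter removal, hemostasis is achieved by manual compression (MC)
or a vascular closure device (VCD). Six access-site complications —
hematoma, retroperitoneal hemorrhage (RPH), arteriovenous fistula (AVF),
pseudoaneurysm (PSA), limb ischemia, infection — are modeled as independent
events. For a strategy with device-failure probability *f* and fallback MC:

- effectiveness (expected complications per catheterization):
  *E = (1−f) Σ<sub>c</sub> r<sub>c</sub><sup>dev</sup> + f Σ<sub>c</sub> r<sub>c</sub><sup>MC</sup>*
- complication-attributable cost:
  *C = (1−f) Σ<sub>c</sub> r<sub>c</sub><sup>dev</sup> Σ<sub>t</sub> p<sub>t</sub> cost<sub>t</sub> + f (MC term)*,
  where treatment costs come from DRG difference costing (higher- minus
  lower-weighted catheterization DRG) or distinct DRGs, with a 1:2
  diagnostic:interventional blend in the combined scenario
- incremental analysis: ΔC, ΔE with dominance classification, and
  ICER = ΔC/ΔE (EUR per averted complication) where a trade-off exists.

On top of the tree: per-complication savings, effectiveness sweeps for
hypothetical bleeding-preventing devices, one-way deterministic sensitivity
analysis with tornado ordering, and value-based pricing (cost-saving
premium, efficiency-frontier premium, same-day-discharge savings).

## Worked example

```r
library(vcdvalue)

p     <- paper_fixture("combined")                      # bundled parameterization
sched <- build_cost_schedule(p$drg_table, "combined")   # DRG difference costing
mc    <- evaluate_strategy(p$strategies$MC, sched)
vcd   <- evaluate_strategy(p$strategies$VCD, sched)
mc
#> <vcd_strategy_result> MC: 0.100 complications, total EUR 3,667 (EUR 68 complication-attributable)
vcd
#> <vcd_strategy_result> VCD: 0.116 complications, total EUR 3,706 (EUR 107 complication-attributable)
incremental_analysis(vcd, mc)
#> <vcd_incremental> delta cost EUR 39, prevented -0.016, dominated
```

Per catheterization, manual compression is expected to cost €3,667 (of
which €68 stem from the 0.100 expected complications); the closure-device
strategy costs €3,706 with 0.116 expected complications — it is more
expensive *and* less safe, hence dominated. A hypothetical device that
prevents all bleeding complications earns at most a €4 cost-saving premium:

```r
bleed_free <- make_hypothetical(p$strategies$VCD, c(hematoma = 0, rph = 0))
cost_saving_premium(bleed_free, p$strategies$VCD, sched)
#> <vcd_pricing> cost_saving: premium EUR 4 per catheterization

round_euro(savings_by_complication(p$strategies$VCD, sched))
#>      hematoma           rph           avf           psa limb_ischemia     infection
#>             0             4            27            53            11            10
```

so redesigning towards pseudoaneurysm prevention (€53) would be worth far
more to the payer. `run_all_scenarios()` + `render_report()` print the full
three-scenario table; see the vignette (`vignettes/decision-model.Rmd`) for
the model's assumptions, the sensitivity-analysis machinery, and the
pricing benchmarks.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/vcdvalue.R evaluate --rounded --out out/
Rscript inst/cli/vcdvalue.R price --scenario combined --out out/
```

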