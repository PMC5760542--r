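# meioswitch

Deterministic modelling of **meiotic entry and commitment in fission yeast**
(*Schizosaccharomyces pombe*). Under nitrogen starvation, fission yeast
cells exit the mitotic cycle, mate, and enter meiosis; past a commitment
point the decision is irreversible even if nutrients return. `meioswitch`
implements the regulatory network behind this switch as a tested ODE
simulator with:

* the **Ste11–Mei2–Pat1 subsystem** — nutrient inputs (Tor2, PKA) drive the
  transcription activator Ste11; pheromone signalling (PheS), Mat1-Pm and
  the Pat1 inhibitor Mei3 form the conjugation cascade; Pat1 keeps the
  meiotic inducer Mei2 phosphorylated and inactive until it is itself
  sequestered;
* an **integrated cell-cycle model** (compact Novák–Tyson-style fission
  yeast cycle with division events, a PP2A:B55/Greatwall starvation branch
  and an intracellular nitrogen pool) coupled to the subsystem through
  Cdk1 inhibition of Ste11's promoter binding and PheS stabilisation of
  Rum1;
* **nutrient-shift protocols** (starvation, return-to-growth /
  commitment-window location, the accelerated-division experiments);
* an **in-silico genotype screen** mapping 43 published mutant situations
  to parameter overrides and classifying mating/meiosis phenotypes;
* a **one-parameter bifurcation toolkit** (multi-start equilibrium oracle,
  pseudo-arclength continuation, saddle-node and Hopf detection) used to
  reproduce the double bistable switch in the Ste11 nuclear-import rate and
  the Cdk1-versus-cell-mass diagrams.

## The model in brief

The subsystem is eight ODEs (time in minutes, concentrations
dimensionless). Ste11-driven transcription steps are Hill functions of
nuclear Ste11; the Mei2 phospho-cycle is Michaelis–Menten with small
Michaelis constants (zero-order ultrasensitivity); Pat1:Mei3 binding is
mass action, and free Pat1 is algebraic (`Pat1_T − complex`), so Pat1
conservation is exact. Meiotic commitment arises from the double-negative
loop Ste11n → Mat1-Pm → Mei3 ⊣ Pat1 ⊣ Ste11n: once Mei3 sequesters Pat1,
the import gate on Ste11 stays open and the state is self-sustaining even
after nutrients return and pheromone signalling is switched off. The PheS
loops alone (Ste11n → PheS → Ste11n import, PheS ⊣ Pat1) are bistable but
reversible — they order conjugation before meiosis without committing the
cell. All rate constants are the package's own calibration against the
qualitative mutant panel (see `vignettes/meioswitch-methods.Rmd` and
`genotype_registry()`); defaults ship as plain-text `.ode` files.

## Worked example

```r
library(meioswitch)

pars <- default_parameters()              # bundled calibration
tr   <- simulate_meiosis(pars, starvation_schedule(50), t_end = 400)
ref  <- starved_reference(pars)
sequential_order_check(tr, ref)
```

```
# A tibble: 4 x 3
  observable  threshold crossing_time
  <chr>           <dbl>         <dbl>
1 phes            1.30           66.3
2 mat1pm          0.169         116. 
3 mei3_t          0.613         237. 
4 mei2_active     2.09          249. 
```

Starvation begins at t = 50 min; the four observables cross half of their
wild-type starved plateaus in the order pheromone signalling → Mat1-Pm →
Mei3 → active Mei2 — conjugation strictly precedes meiotic entry. The
return-to-growth experiment brackets the commitment point:

```r
run_return_to_growth(135, pars)$verdict   # "reversible"
run_return_to_growth(150, pars)$verdict   # "irreversible"
commitment_window(pars, resolution = 1)[, 1:2]
```

```
# A tibble: 1 x 2
  t_reversible_max t_irreversible_min
             <dbl>              <dbl>
1             143.               144.
```

Re-adding nitrogen (and silencing pheromone signalling) at 135 min lets
Pat1 recover and re-inactivate Mei2; by 150 min enough Pat1:Mei3 complex
has formed that the switch completes regardless — the window of
opportunity closes between 143 and 144 minutes after starvation. The
genotype screen and its concordance with the published phenotype calls:

```r
sc <- run_screen(params = pars)
glance(sc)
```

```
# A tibble: 1 x 4
  n_strains n_scored n_matched concordance
      <int>    <int>     <int>       <dbl>
1        43       43        43           1
```

`autoplot(tr)`, `plot_branches(scan_import_rate(pars))` and
`autoplot(sc)` give quick-look figures; `tidy()`/`glance()` methods return
plain tibbles for downstream work.

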