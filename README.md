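# cochleaEP

An R package that simulates the electrochemical circuit maintaining the
**endocochlear potential (EP)** — the +80 mV standing potential of cochlear
endolymph that makes mammalian hearing possible. It is aimed at inner-ear
physiologists and systems biologists who want a tested, scriptable model of
the cochlear lateral wall: how the K⁺ **circulation current** arises from
ion channels and Na⁺,K⁺-ATPases arranged in series across six membrane
domains, and how EP collapses when the syncytial pumps are blocked
(perilymphatic ouabain).

## The model in one paragraph

Six membrane domains in a closed loop — hair-cell apical (HA, resting MET
channels) and basolateral (HB), syncytial basolateral (SB: Na⁺,K⁺-ATPase +
Na⁺ conductance + leak, no Cl⁻ transport) and apical (SA, Kir-type K⁺),
marginal-cell basolateral (MB) and apical (MA, KCNQ-type K⁺) — connect six
compartments (perilymph, syncytium, 15-nm intrastrial space, marginal cell,
hair cell, endolymph). With membrane potentials measured intracellular minus
extracellular:

```
EP  = v_SB - v_SA + v_MB - v_MA          ISP = v_SB - v_SA
v_HA = v_HB - EP                         I_cir = -G_MET (v_HA - RT/F ln([K]_EL/[K]_HC))
dv/dt   = (sigma * I_cir - I_M) / C      (sigma = +1 out-of-cell, -1 into-cell membranes)
d[X]/dt = net molar flux / V             I_channel = G (v - E_X),  pump 3 Na⁺ : 2 K⁺
```

Under-constrained parameters are **calibrated** so the measured operating
point (EP +72.7 mV, v_SB +9.6 mV, [K⁺]_SY 98.3 mM, ISP +81.2 mV, [K⁺]_IS
6.1 mM, 3 nA loop) is an exact steady state; the SB triple (pump activity,
Na⁺ conductance, leak) solves the basolateral flux-balance system with a
documented ratio closure. Ouabain blockade is an activity step: `kappa` is
the *remaining* pump activity (0.46 reproduces the 10 µM condition).

See `vignettes/lateral-wall-model.Rmd` for the full account: equations, sign
conventions, every default with units and rationale, numerical methods, and
what the bundled fallback parameterisation does and does not reproduce.

## Worked example

```r
library(cochleaEP)
model <- reference_model()                     # bundled calibrated fixture

normal <- run_normal_steady(model)             # 600-s settle + root-find
block  <- run_ouabain_block(model, kappa = 0.46)
print(normal)
```

```
<lw_report> normal steady state
 observable simulated reference unit tolerance pass
         EP      72.7      72.7   mV       0.5 TRUE
       v_SB       9.6       9.6   mV       0.5 TRUE
       K_SY      98.3      98.3   mM       0.5 TRUE
        ISP      81.2      81.2   mV       0.5 TRUE
       K_IS       6.1       6.1   mM       0.5 TRUE
                                  location
 validation-table, simulated normal column
 ...
config 4abb92e8
```

The five observables sit on the calibrated operating point: the +72.7 mV EP
is carried almost entirely by the +81.2 mV intrastrial potential, and the
3 nA circulation current flows through every membrane domain. Blockade at
`kappa = 0.46` collapses EP and syncytial K⁺; the circulation current
(plotted in the SB membrane orientation, `-I_cir`) settles at **−1.89 nA**
and the outward pump Na⁺ current stays at **2.58 nA** throughout:

```r
y40 <- attr(block$series, "states")[nrow(block$series), ]
plateau <- find_steady_state(model, state0 = y40, factors = c("SB/nak_atpase" = 0.46))
-system_state(model, plateau)$I_cir     # -1.89  (nA)
system_state(model, plateau)$EP         # +12.2  (mV)
block$pump_na_range                     # 2.577 2.577  (nA)
```

With the bundled fallback kinetics the collapse is slower than the
published dynamics (time constants ~4–7× longer), so the 40-min samples are
still en route; `tests/testthat/test-acceptance.R` asserts those published
targets faithfully and leaves them red, with the analysis in the vignette.

## Command line

Every run is driven by a JSON configuration (schema-validated; the bundled
fixture at `inst/extdata/reference_config.json` is the worked reference,
with a provenance note on every element magnitude):

```sh
Rscript -e 'quit(status = cochleaEP::lw_cli())' steady     --config ref.json --out run0/
Rscript -e 'quit(status = cochleaEP::lw_cli())' block      --config ref.json --kappa 0.46 --t-end 2400 --out run1/
Rscript -e 'quit(status = cochleaEP::lw_cli())' scan-kappa --config ref.json --from 0.30 --to 0.60 --step 0.01 --out run2/
Rscript -e 'quit(status = cochleaEP::lw_cli())' calibrate  --config ref.json --out run3/
Rscript -e 'quit(status = cochleaEP::lw_cli())' decompose  --config ref.json --out run4/
```

Outputs are CSV time series (`time_s, v_SB, ..., v_HA, EP, ISP, I_cir`,
then `<ion>_<compartment>` columns), CSV reports, and a `run_log.txt`
recording solver settings and the configuration hash.

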