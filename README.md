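# pdregio

Mechanism classification and regioselectivity prediction for
Pd(II)/acetate-catalysed aromatic C–H activation.

## The problem

Palladium diacetate activates aromatic C–H bonds through two competing
mechanisms: **proton abstraction** (PA, the concerted
metalation–deprotonation pathway in which an acetate ligand removes the
proton as the Pd–C bond forms) and **electrophilic aromatic substitution**
(SEAr, in which Pd(II) attacks the arene and forms a Wheland-type *ipso*
complex with the hydrogen still attached). Which mechanism operates, and
which ring position reacts, decides the product — and guessing wrong costs
bench time. Because both pathways proceed through relatively unstable
Pd–substrate intermediates, the Hammond postulate lets the *relative Gibbs
energies of those intermediates* stand in for the kinetic barriers, so a
screening calculation over every candidate intermediate can rationalise both
the mechanism and the site selectivity without locating transition states.

`pdregio` implements that screening pipeline for computational and synthetic
chemists:

1. **Site enumeration** — parse a substrate (SMILES or MOL), perceive
   aromaticity, and list the symmetry-unique aromatic C–H positions
   (`H1`, `H2`, …).
2. **Intermediate construction** — embed 3D conformers and place a
   Pd(OAc)₂ template at every site in both mechanistic geometries
   (ipso complex for SEAr; acetate oxygen directed at the C–H proton
   for PA).
3. **Screening** — a 5-iteration quick optimization with a group-relative
   10 kcal·mol⁻¹ energy pre-screen, then full optimization + frequency
   analysis under an automated remediation state machine (saddle point →
   displace along the imaginary mode and resubmit; stale Hessian → restart
   from the last geometry; hopeless initial guess or decomposed
   intermediate → discard). Optimized intermediates must retain a Pd–C bond
   of at most **2.4 Å**.
4. **Classification** — the *ipso-complex stability parameter*

   Δ = [G<sub>min</sub>(PA) − G<sub>min</sub>(SEAr)] × 627.5095 kcal·mol⁻¹

   is thresholded: Δ < 0 → PA; Δ > 5 → SEAr; 0 ≤ Δ ≤ 5 → both mechanisms
   plausible. A mechanism with no surviving intermediate forfeits outright.
5. **Product ratios** — per-site Boltzmann weights
   fᵢ = exp(−ΔΔGᵢ/RT) / Σⱼ exp(−ΔΔGⱼ/RT) at 298.15 K (configurable).

Engine execution is deliberately out of process: the package writes
NWChem-dialect input decks and parses NWChem-dialect logs, and ships two
desk-scale backends — a **tabulated** backend replaying bundled validation
tables and a **synthetic** backend with known ground truth — so the entire
decision layer runs and tests without a quantum-chemistry engine.

## Worked example

Entry 4 of the bundled heteroaromatic validation set, through the tabulated
backend:

```r
library(pdregio)

fx      <- load_paper_fixtures()
backend <- tabulated_backend(fx$energies,
                             deltas = fx$table2_meta[, c("substrate_id", "delta_kcal")])
report  <- predict_mechanism("t2e4", backend)
report
#> <ch_report> substrate t2e4
#>   mechanism call: PA (THRESHOLD), stability parameter -2.0000 kcal/mol
#>   PA sites: H6:0.0 (96%)  H1:1.9 (4%)  H5:9.8 (0%)
#>   SEAR sites: H1:0.0 (98%)  H3:2.9 (1%)  H4:2.9 (1%)  H2:3.9 (0%)  H5:4.2 (0%)
```

The stability parameter is negative, so the substrate is called **PA**; the
0.0 kcal·mol⁻¹ site of the PA table (`H6`) is the predicted reaction centre,
and the Boltzmann fractions say the H6 product should dominate 96:4 over H1.
`tidy(report)` returns the site table as a tibble, `glance(report)` a
one-row summary, and `autoplot(report)` the site-energy profile:

```r
glance(report)
#> # A tibble: 1 × 8
#>   substrate_id delta_kcal call  basis     n_sites_pa n_sites_sear top_site_pa
#>   <chr>             <dbl> <chr> <chr>          <int>        <int> <chr>
#> 1 t2e4              -2.00 PA    THRESHOLD          3            5 H6
```

The structure route runs the same pipeline from a SMILES string:

```r
furan  <- parse_substrate("c1ccoc1", "furan")
enumerate_ch_sites(furan)        # two unique sites: alpha and beta
predict_mechanism(furan, synthetic_backend(seed = 3, mech_offset = -3))
```

A thin command-line wrapper covers scripted use:

```sh
Rscript inst/cli/pdregio.R classify --delta 7.2        # -> SEAR (THRESHOLD)
Rscript inst/cli/pdregio.R predict --substrate-id t2e8 \
        --backend tabulated --table paper_tables.csv --out runs/
```

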