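# porescope

Structural and trajectory analysis of pentameric ligand-gated ion channels,
centred on the synaptic α1β2γ2 GABA-A receptor and the question of how
neurosteroids modulate it: positive modulators such as allopregnanolone
dilate the pore and stabilise the agonist, while sulfated neurosteroids
(pregnenolone sulfate, DHEAS) act as pore blockers wedged between the −2′
and 9′ gates. The package is written for structural biologists and
simulators who want those analyses as reproducible, tested functions rather
than one-off scripts.

## What it computes

* **Pore radius profiles** — the maximal inscribed-sphere radius along the
  channel axis, `R(z) = max_c min_i (|c − x_i| − r_vdW,i)` with sphere
  centres `c` confined to the plane at `z`, found by a deterministic
  grid + Nelder–Mead search that tracks the pore lumen; per-prime-position
  gate diameters `d(k′) = 2 min R(z)` over a ±1.5 Å slab around each M2
  ring (M2 prime numbering −2′…20′, with the 9′ leucine activation gate and
  the −2′ desensitisation gate).
* **Ligand dynamics** — RMSD traces after Cα superposition (Kabsch),
  with an optional crop rule for unbinding excursions; signed displacement
  of the ligand centre of mass along the pore axis; quality-threshold pose
  clustering on the pairwise ligand-RMSD matrix (default 1 Å cutoff, 10
  clusters) with medoid representatives.
* **Contact fingerprints** — per-residue contact frequencies at a 4.5 Å
  any-heavy-atom criterion, replicate mean ± sd, and the ≥ 50 % frequent-
  contact rule, with prime-position annotation.
* **Ensemble metrics** — waters within 3 Å of the 9′ gate per frame, and
  the upper-ECD spread (radial dispersion of the five subunits' upper-ECD
  centres of mass, or their COM displacement).
* **Permeation energetics** — Boltzmann inversion
  `F(z) = −k_B T ln ρ(z)` of 1-d ion samples (with bias reweighting),
  barrier extraction over a gate window, and a reflecting-bounds Metropolis
  sampler serving as the recovery oracle.
* **Synthetic data** — seeded generators for pseudo-C5 pentameric channels
  with analytically known pore profiles, trajectories with programmed
  ligand jitter/drift, contact schedules, gate hydration and ECD breathing,
  and state stand-ins whose calibrated geometry emulates the published gate
  diameters of agonist-alone (4.6 Å at 9′), +allopregnanolone (9.1 Å),
  +etomidate (8.4 Å) and +propofol (10.5 Å) structures.

## Worked example

```r
library(porescope)

ch <- synthetic_state_channel("gaba_allo")        # dilated-pore stand-in
sm <- infer_subunit_map(ch$structure)             # 2 alpha / 2 beta / 1 gamma
pm <- build_prime_map(ch$structure, sm)           # -2'..20' per chain
al <- align_pore_axis(ch$structure, sm, pm)       # pseudo-C5 axis -> +z
prof <- pore_profile(al$structure)                # inscribed-sphere R(z)
gd <- gate_diameters(prof, pm, al$structure)
gd[gd$prime %in% c(-2, 9), c("prime", "diameter")]
#>   prime diameter
#> 1    -2 2.399346
#> 2     9 9.099184
```

The −2′ gate stays constricted (~2.4 Å, the desensitisation-gate hallmark)
while the 9′ activation gate reads 9.1 Å — the programmed dilated-state
geometry, recovered by the full measurement pipeline. Running the numbered
scripts under `analysis/` reproduces the whole study on simulated systems:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

which writes profiles, gate tables, ligand traces, cluster results,
contact fingerprints, hydration/spread traces and free-energy profiles
under `results/`, printing for instance the gate summary

```
     state diameter_9prime diameter_minus2prime
      gaba        4.599716             2.399346
 gaba_allo        9.099184             2.399346
 etomidate        8.399042             2.598907
  propofol       10.498898             2.598907
```

and the recovered chloride-barrier ordering
`6.92 < 17.76 < 31.49 kJ/mol` for programmed barriers of 7, 18 and 32.

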