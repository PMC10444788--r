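# Deposited coordinate files (not redistributed)

The desk-scale structural checks operate on experimentally deposited
coordinates of the alpha1-beta2-gamma2 GABA-A receptor, which are not
shipped with the package. To run them, download the entries below from the
Protein Data Bank (e.g. `https://files.rcsb.org/download/<ID>.pdb`) and
place them in this directory as `<ID>.pdb`:

| Accession | State                           |
|-----------|---------------------------------|
| 6X3Z      | GABA alone                      |
| 8SI9      | GABA + allopregnanolone         |
| 6X3V      | GABA + etomidate                |
| 6X3T      | GABA + propofol                 |
| 8SGO      | GABA + pregnenolone sulfate (optional) |
| 8SID      | GABA + DHEAS (optional)         |

Without these files the corresponding checks in
`tests/testthat/test-acceptance.R` report failure; every other analysis in
the package runs on synthetic, ground-truthed data and needs no downloads.
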