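# Bundled gene-set fixtures

Both GMT files here are **synthetic stand-ins** whose member gene ids match
the layout of the simulated cohort produced by `analysis/01_simulate.R`
(2000 genes, 1% mitochondrial prefix `Mt-`, marker blocks starting at
`gene00021`). They exist so the drivers and examples can run end-to-end
without external downloads.

* `marker_panels_synthetic.gmt` — microglia / macrophage / neuron marker
  panels aligned with the generator's planted cluster marker blocks.
* `state_sets_synthetic.gmt` — M1 / M2 / metabolism state sets drawn from
  non-marker genes.

For real analyses, supply curated marker and state gene lists in GMT
format in their place.
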