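# Demo pipeline configuration: bundled toy model + synthetic cohort.
# Paths are resolved relative to the working directory; the gmt/ppi
# entries below assume you copied the packaged fixtures, e.g.
#   file.copy(system.file("extdata", c("toy_gene_sets.gmt",
#             "toy_ppi_edges.tsv"), package = "fluxdiff"), ".")
seed: 1
out_dir: fluxdiff_demo
fdr_alpha: 0.05
lfc_min: 0.01
percentile: 0.95
reps: 30
subsample_frac: 0.8
network_threshold: 0.5
ppi_score_min: 0.4
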