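The correlation network connects pairs of features whose intensities co-vary
strongly across samples (absolute correlation at least {r_threshold} with FDR
at most {fdr_threshold}). Of {n_nodes} features, {n_edges} pairs pass both
thresholds. Densely connected modules often correspond to related chemistry -
in-source fragments, adducts and isotopes of one compound, or members of one
biochemical pathway - and are natural starting points for annotation.
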