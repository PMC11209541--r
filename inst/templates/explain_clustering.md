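Hierarchical clustering groups {axis} by the similarity of their profiles
({distance} distance, {linkage} linkage). The heatmap shows the data with rows
and columns arranged by the clustering, so blocks of colour correspond to sets
of features behaving coherently across sets of samples. Samples from the same
biological group merging at low heights confirm the group structure seen in
the ordination plots.
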