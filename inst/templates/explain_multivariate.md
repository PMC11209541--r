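Principal component analysis (PCA) is an unsupervised summary of the
preprocessed data: samples that sit close together have similar overall
metabolic profiles. The first component explains {pc1_pct} of the total
variance and the second {pc2_pct}. Tight clustering of the pooled-QC samples
indicates good technical reproducibility, while separation between biological
groups indicates metabolic differences larger than the within-group
variation. {plsda_sentence}
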