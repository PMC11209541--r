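The submitted dataset contains {n_features} mass features measured across
{n_samples} samples ({n_qc} pooled-QC injections) in {n_groups} biological
groups. {missing_pct} of intensity cells are missing, which is typical of
peak-picked LC-MS data where low-abundance features fall below the detection
limit in some injections. Missing cells are handled by the imputation step of
preprocessing before any statistics are computed.
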