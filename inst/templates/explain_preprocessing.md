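Preprocessing turns the raw feature table into clean data suitable for
statistics. The stages ran in the fixed order shown in the provenance table:
imputation, QC-based RSD filtering, normalization, log10 transformation and
scaling. {n_removed} features exceeded the QC relative-standard-deviation
threshold and were removed as technically unstable; {n_kept} features remain.
Per-sample normalization factors ranged from {factor_min} to {factor_max}; a
wide range indicates substantial sample-to-sample variation in overall signal
(for example dilution differences) that normalization has corrected. After
log10 transformation and scaling, feature distributions are approximately
symmetric and features contribute on comparable scales to the multivariate
analyses below.
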