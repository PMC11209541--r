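Each feature was tested with a {test_name}. P-values were adjusted for
multiple testing with the Benjamini-Hochberg procedure, which controls the
false-discovery rate (FDR): among features reported at FDR < 0.05, about 5%
are expected to be false leads. {n_sig} of {n_tested} features are significant
at FDR < 0.05. Fold changes are computed on the positive, untransformed
intensity scale, so a fold change of 2 means the feature's mean intensity is
twice as high in the first group. The volcano plot combines both views:
features to the far left or right differ strongly in magnitude, features near
the top are statistically most reliable, and the interesting candidates sit in
the upper corners.
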