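This report summarizes an untargeted metabolomics analysis of the mass-feature
table submitted for project "{project_name}". Mass features (m/z, retention-time
peaks quantified per sample) were preprocessed to remove technical variation,
then examined with univariate and multivariate statistics. Each section below
states the method and parameters used, shows the resulting tables and figures,
and explains how to read them. All tables and figures are embedded in this
single HTML file, so the report can be archived and shared as one
self-contained document.
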