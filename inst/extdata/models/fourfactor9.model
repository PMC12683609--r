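# Four correlated latent factors over nine psychiatric GWAS traits:
# a European psychosis factor, an Asian psychosis factor (with a small
# negative cross-loading of BD2_JPN from F1), a bipolar factor and a
# depression factor.
factor F1: SCZ_EUR BD1_EUR BD2_JPN
factor F2: SCZ_EAS SCZ_JPN BD2_JPN
factor F3: BD1_EUR BD2_EUR BD1_JPN
factor F4: BD1_JPN MDD_EUR MDD_EAS
covary all
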