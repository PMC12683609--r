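# Three-factor alternative: a single psychosis factor pooling the European
# and Asian schizophrenia traits, plus bipolar and depression factors.
factor F1: SCZ_EUR BD1_EUR SCZ_EAS SCZ_JPN BD2_JPN
factor F2: BD1_EUR BD2_EUR BD1_JPN
factor F3: BD1_JPN MDD_EUR MDD_EAS
covary all
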