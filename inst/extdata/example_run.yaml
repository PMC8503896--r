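# Example session configuration for `histannot simulate --config`.
# Keys not listed fall back to default_run_config().
kind: nuclei
height: 512
width: 512
density: 250
seed: 7
patch_size: 128
patches_per_round: 4
rounds: 2
epochs_per_round: 6
pretrain_epochs: 1
accept_threshold: 0.9
correction_fidelity: 1.0
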