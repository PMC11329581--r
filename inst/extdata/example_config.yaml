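# Annotated run configuration for the receptorgan command-line interface.
# Precedence: CLI flag > this file > built-in defaults. Every stage writes
# the fully resolved configuration (resolved_config.yaml) next to its
# outputs.

synthetic:                      # paired-section simulator (SyntheticSpec)
  area: V1                      # V1 or M1
  receptor: M2                  # M2 or kainate
  canvas_px: [48, 96]           # (height, width) at receptor resolution
  receptor_resolution_um: 125   # receptor pixel size, micrometres
  resolution_factor: 16         # cyto grid is this many times finer
  ribbon_thickness_mm: 2.0      # simulated cortical thickness
  curvature: straight           # straight | sinusoid | sulcus
  curvature_amplitude_mm: 0.5   # midline undulation amplitude
  noise_sd: [0.05, 0.02]        # additive noise sd: [cyto, receptor]
  intensity_jitter: 0.1         # labeling-intensity variation amplitude
  deformation_amplitude_px: 2   # max synthetic displacement, receptor px
  seed: 1                       # master seed (overridden by --seed)

dataset:
  n_sections: 2                 # synthetic sections to simulate
  interval_mm: 0.2              # midline stepping interval
  offsets_mm: [-0.5, 0, 0.5]    # offset set (Cartesian product in x, y)
  min_coverage: 0.98            # tissue-coverage threshold for windows
  max_pairs: .na                # optional cap on written pairs

training:                       # TrainingConfig fields
  variant: single_area          # single_area | cond_multi_area | uncond_multi_area
  gamma: 0.5                    # adversarial / L1 balance
  learning_rate: 0.001
  beta1: 0.5
  beta2: 0.99
  epochs: 250                   # full-scale default; reduce for smoke runs
  batch_size: 8
  clip_norm: 1.0                # global gradient-norm clip
  seed: 1
  train_fraction: 0.8           # section-level train share

evaluate:
  noise_seed: 1                 # seed stream for generation at evaluation
  fid_seed: 7                   # builtin feature-extractor weight seed

seed: 1                         # global fallback seed
log_level: info
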