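# Example experiment configuration for the siamreg CLI.
# All fields mirror the package's networkConfig / lossConfig / trainConfig
# defaults; omit a field to use the default.

simulate:
  n_pairs: 12
  extents: [48, 48, 48]
  spacing: 0.6           # mm, isotropic
  # crop_to: [40, 40, 48]  # uncomment for a cross-scale (cropped moving) set
  deform:
    controlSpacing: 12   # control-point spacing, voxels
    amplitude: 3         # max displacement, voxels
    sigma: 2             # Gaussian smoothing of the field, voxels

network:
  levels: 3              # pooling depth; inputs must divide by 2^levels
  baseChannels: 16
  firstKernel: 7
  innerKernel: 3
  useLabelChannels: true
  padMode: symmetric
  fieldSigma: 1          # Gaussian smoothing of the displacement output

loss:
  sigmaSet: [0, 1, 2, 4, 8]
  alpha: 0.5
  smoothVariant: gradient
  epsilon: 1.0e-6

train:
  learningRate: 1.0e-4
  iterations: 10000
  batchSize: 2
  checkpointInterval: 15
  folds: 4
  adamEpsilon: 1.0e-5
  warmupIters: 50        # linear learning-rate warm-up
  lrDecayFactor: 1       # optional late step decay (1 = constant rate)
  lrDecayAt: 0.667
  augmentFlip: true
  augmentAffine: true
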