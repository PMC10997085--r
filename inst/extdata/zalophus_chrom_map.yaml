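contigs:
  NC_045612.1: X_LIKE
  NC_045613.1: Y_LIKE
default: AUTOSOME
labels:
  homogametic: female
  heterogametic: male
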