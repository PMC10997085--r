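contigs:
  chrA: AUTOSOME
  chrX: X_LIKE
  chrY: Y_LIKE
default: AUTOSOME
labels:
  homogametic: female
  heterogametic: male
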