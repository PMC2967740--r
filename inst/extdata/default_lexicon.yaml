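low_terms:
  - might
  - may
  - could
high_terms:
  - should
  - will
  - are
  - is
  - must
  - was
  - do
consequence_terms:
  - risk
  - caution
  - adverse
  - toxicity
  - bleeding
  - fatal
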