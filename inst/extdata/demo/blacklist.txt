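# common false positives suppressed from concept matching
# (normalised with the same stemming pipeline as dictionary keys)
earth
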