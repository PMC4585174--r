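# the scaled-down printed-value block reports every deviation rather
# than stopping at testthat's default failure cap
options(testthat.progress.max_fails = 1000)
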