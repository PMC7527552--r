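acc1	wild
acc2	wild
acc3	cult
acc4	cult
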