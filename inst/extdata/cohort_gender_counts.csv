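group,female,male
CTRL,46,40
MDD,27,23
BP,27,19
SCZ,19,40
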