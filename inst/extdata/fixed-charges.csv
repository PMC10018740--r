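# Fixed point-charge presets for nonpolarizable embedding (units of e).
set,element,charge
tip3p-charges,O,-0.834
tip3p-charges,H,0.417
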