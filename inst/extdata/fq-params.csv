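# Fluctuating-charge parameter sets (atomic units).
# chi: atomic electronegativity; eta: chemical hardness.
# "water-radical": water parameters of the electronegativity-equalization
# lineage tuned for electrostatics/polarization of radicals in aqueous
# solution (Rick-Stuart-Berne-derived convention).
set,element,chi,eta
water-radical,O,0.189194,0.523700
water-radical,H,0.012767,0.537512
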