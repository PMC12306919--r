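# Sixteen 6-mm-diameter spherical stress-processing ROIs (MNI mm).
# Coordinates are stored exactly as published. Two entries are internally
# inconsistent in the source and kept as printed rather than corrected:
#   - "Left amygdala" has z = +14 while the right amygdala has z = -14
#     (possible sign typo).
#   - rows 3 and 4 pair the label sides Right/Left with x = -32 / +32.
# Repeated region names are disambiguated with a " (2)" / " (3)" suffix so
# labels are unique; source_note preserves the printed region name.
label,x,y,z,diameter,source_note
Right insula/BA 13,36,22,0,6,Right insula/BA 13
Left insula/BA 13,-36,22,0,6,Left insula/BA 13
Right insula/BA 13 (2),-32,20,4,6,Right insula/BA 13
Left insula/BA 13 (2),32,20,4,6,Left insula/BA 13
Right basal ganglia,14,0,-2,6,Right basal ganglia
Left basal ganglia,-14,0,-2,6,Left basal ganglia
Right parahippocampal gyrus,18,-6,-18,6,Right parahippocampal gyrus
Right amygdala,20,-4,-14,6,Right amygdala
Left amygdala,-20,-4,14,6,Left amygdala (z as printed; possible sign typo)
Left superior frontal gyrus/BA 25,-8,52,38,6,Left superior frontal gyrus/BA 25
Left precuneus/BA 7,-22,-48,50,6,Left precuneus/BA 7
Left putamen,-14,12,-10,6,Left putamen
Left thalamus,-10,2,4,6,Left thalamus
Left insula/BA 13 (3),-46,4,-4,6,Left insula/BA 13
Left inferior frontal gyrus/BA 9,-44,14,22,6,Left inferior frontal gyrus/BA 9
Left parahippocampal gyrus/BA 28,-18,-4,-16,6,Left parahippocampal gyrus/BA 28
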