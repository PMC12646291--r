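schema_version: 1.0

factor: bmi
kind: threshold
threshold: 30
at_boundary: above
above: 2
below: 1

factor: sex
kind: binary
levels: male female
positive: male
yes: 2
no: 1

factor: hairy_back
kind: flag
yes: 2
no: 1

factor: diabetes
kind: flag
yes: 3
no: 1

factor: prior_recurrence
kind: flag
yes: 3
no: 1

factor: n_midline_pits
kind: bins
breaks: 5 10
points: 2 4 6

factor: lateral_pits
kind: flag
yes: 3
no: 1

factor: distance_to_anus_cm
kind: threshold
threshold: 5
at_boundary: below
above: 1
below: 3

factor: prior_abscess
kind: flag
yes: 3
no: 1
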