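pattern	label_type	value	confidence	keyed_only
male	sex	male	1.0	FALSE
m	sex	male	1.0	FALSE
man	sex	male	1.0	FALSE
1	sex	male	0.5	TRUE
female	sex	female	1.0	FALSE
f	sex	female	1.0	FALSE
woman	sex	female	1.0	FALSE
0	sex	female	0.5	TRUE
y	age_unit	years	1.0	FALSE
yr	age_unit	years	1.0	FALSE
yrs	age_unit	years	1.0	FALSE
year	age_unit	years	1.0	FALSE
years	age_unit	years	1.0	FALSE
mo	age_unit	months	1.0	FALSE
mos	age_unit	months	1.0	FALSE
mon	age_unit	months	1.0	FALSE
month	age_unit	months	1.0	FALSE
months	age_unit	months	1.0	FALSE
w	age_unit	weeks	1.0	FALSE
wk	age_unit	weeks	1.0	FALSE
wks	age_unit	weeks	1.0	FALSE
week	age_unit	weeks	1.0	FALSE
weeks	age_unit	weeks	1.0	FALSE
d	age_unit	days	1.0	FALSE
day	age_unit	days	1.0	FALSE
days	age_unit	days	1.0	FALSE
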