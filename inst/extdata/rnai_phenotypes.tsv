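tf_id	affected	categories
Chrac-14	TRUE	A6_female_only
hb	TRUE	A6_female_only
Hesr	TRUE	A6_female_only
Hr38	TRUE	A6_female_only
Lim3	TRUE	A6_female_only
noc	TRUE	A6_female_only
SoxN	TRUE	A6_female_only
Abd-B	TRUE	A5_A6_reduced
CG30020	TRUE	A5_A6_reduced
fru	TRUE	A5_A6_reduced
sima	TRUE	A5_A6_reduced
Sox102F	TRUE	A5_A6_reduced
brm	TRUE	multi_segment_reduced
C15	TRUE	multi_segment_reduced
CG1845	TRUE	multi_segment_reduced
lab	TRUE	multi_segment_reduced
sd	TRUE	multi_segment_reduced
vvl	TRUE	multi_segment_reduced
Tip60	TRUE	increased
CG11984	TRUE	increased
bab1	TRUE	increased
ato	TRUE	A6_female_only,increased
BEAF-32	TRUE	A6_female_only,increased
dsx	TRUE	A5_A6_reduced,increased
Eip78C	TRUE	A6_female_only,increased
Hr46	TRUE	A6_female_only,increased
Hr78	TRUE	A6_female_only,increased
jing	TRUE	multi_segment_reduced,increased
Met	TRUE	A6_female_only,increased
pnt	TRUE	A6_female_only,increased
Su(z)12	TRUE	A5_A6_reduced,increased
ush	TRUE	A6_female_only,increased
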