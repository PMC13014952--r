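state,effective_date,covariate_complete
AL,,1
AK,,1
AZ,,1
AR,,1
CA,2016-01-01,1
CO,2019-01-01,1
CT,1999-10-01,0
DE,2018-12-27,1
FL,2018-03-09,1
GA,,1
HI,2020-01-01,1
ID,,0
IL,2019-01-01,1
IN,2005-07-01,1
IA,,1
KS,,1
KY,,1
LA,,1
ME,,0
MD,2018-10-01,1
MA,2018-08-17,1
MI,,1
MN,,1
MS,,1
MO,,1
MT,,1
NE,,1
NV,2020-01-01,1
NH,,0
NJ,2019-09-01,1
NM,2020-05-20,1
NY,2019-08-24,1
NC,,1
ND,,0
OH,,1
OK,,1
OR,2018-01-01,1
PA,,1
RI,2018-06-01,1
SC,,1
SD,,0
TN,,1
TX,,0
UT,,1
VT,2018-04-11,1
VA,2020-07-01,1
WA,2016-12-08,1
WV,,1
WI,,1
WY,,0
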