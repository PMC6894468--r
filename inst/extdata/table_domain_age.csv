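# Age-bin composition of everyday-domain engagers with published
# deviations from the cross-activity average, re-keyed from a 2307-adult
# time-use study. Population shares: 33/40/10/17 across <20, 20-39,
# 40-59, 60+.
activity,n,<20,20-39,40-59,60+,dev_<20,dev_20-39,dev_40-59,dev_60+
Sleep,2307,31,41,11,17,0,1,0,-1
Self-care,2306,32,41,11,17,0,1,0,-1
Social,2167,31,40,11,18,0,0,0,-1
Passive Transport,2154,31,41,11,17,0,1,0,-1
Screen Time,2125,31,40,11,18,0,0,0,0
Chores,2107,29,41,12,18,-2,1,1,0
Work and Study,2026,32,41,11,15,1,1,0,-3
Quiet Time,2011,30,39,12,19,-1,-1,1,1
Active Transport,1984,31,39,12,18,-1,-1,1,0
Exercise and Sport,1261,35,41,9,16,4,1,-2,-2
Cultural,313,30,34,9,27,-1,-6,-2,8
Average,,31,40,11,18,,,,
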