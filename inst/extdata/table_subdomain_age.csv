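# Age-bin composition of Exercise and Sport sub-domain engagers with
# published deviations from the cross-activity average, re-keyed from a
# time-use study (demographic base n = 2238).
activity,n,<20,20-39,40-59,60+,dev_<20,dev_20-39,dev_40-59,dev_60+
Gym,754,33,41,8,18,-5,1,1,4
Non-Team Sports,514,36,38,11,15,-2,-2,4,1
Team Sports,317,53,40,3,3,15,0,-4,-11
Active Play,127,26,37,13,24,-12,-3,6,10
Games,90,46,43,2,9,8,3,-5,-5
Dance,83,36,42,7,14,-2,2,0,0
Average,,38,40,7,14,,,,
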