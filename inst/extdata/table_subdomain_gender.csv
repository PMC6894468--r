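# Gender composition of Exercise and Sport sub-domain engagers with
# published deviations from the cross-activity average, re-keyed from a
# time-use study (demographic base n = 2238). The Games proportions are
# re-keyed as printed (67 + 34 = 101 due to the authors' rounding).
activity,n,male,female,dev_male,dev_female
Gym,754,48,52,-1,-1
Non-Team Sports,514,48,52,-1,-1
Team Sports,317,63,37,14,-16
Active Play,127,35,65,-14,12
Games,90,67,34,18,-19
Dance,83,24,76,-25,23
Average,,49,53,,
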