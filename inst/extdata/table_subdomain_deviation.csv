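# Deviations (observed duplication minus column-average duplication, in
# percentage points) among six Exercise and Sport sub-domains, re-keyed
# from the published deviation table (base: 1261 engagers). The authors
# computed on unrounded data, so some cells differ by 1 pp from what the
# rounded duplication table reproduces.
activity,prevalence,Gym,Non-Team Sports,Team Sports,Active Play,Games,Dance
Gym,60,,1,0,0,-2,0
Non-Team Sports,41,8,,5,0,0,1
Team Sports,14,4,5,,-2,2,-1
Active Play,10,-4,-5,-6,,0,0
Games,7,-9,-3,8,1,,0
Dance,7,2,3,-7,1,-1,
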