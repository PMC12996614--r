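# Illustrative validated fusion gene set (synthetic example; the
# diagnostic gene list is site configuration).
ALK
RET
ROS1
MET
NTRK1
NTRK2
NTRK3
FGFR2
FGFR3
EGFR
ERG
NRG1
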