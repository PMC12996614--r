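# Illustrative recurrent-breakpoint table (synthetic example values).
# The diagnostic table of recurrent breakpoints is site configuration and
# must be supplied by the user; only ALK's boundary after exon 19 is a
# widely known recurrent breakpoint, the other rows are placeholders
# showing the schema.
gene_id	boundary_exon	retained_side
ALK	19	3prime
RET	11	3prime
ROS1	33	3prime
MET	13	3prime
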