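lichen_taxon,host_taxon,cell_id,area_id
L1,H1,U1,A
L1,H2,U2,A
L2,H1,U1,A
L2,H1,U3,B
L2,H1,U1,A
L3,H2,U3,B
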