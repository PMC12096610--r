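diet,rel_gn,rel_gaa,gn,gaa
RGR_HGR,1.23,1.28,14.80,0.57
MRGR_MHGR,1.22,1.40,14.70,0.62
MGR_MGR,1.54,1.63,18.60,0.72
MSGR_MLGR,0.53,0.41,6.41,0.18
SGR_LGR,1.32,0.71,16.00,0.31
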