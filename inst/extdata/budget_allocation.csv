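region,quantity,value
SEA,cost_cervical,781881006
SEA,cost_breast,1454645503
SEA,cost_colorectal,364949796
SEA,cost_total,2601476305
SEA,hly_undiscounted,8611060
SEA,hly_discounted,1830047
SEA,programme_acer,302.11
SEA,share_cervical,30
SEA,share_breast,56
SEA,share_colorectal,14
ESSA,cost_cervical,1522549019
ESSA,cost_breast,1635269849
ESSA,cost_colorectal,248737875
ESSA,cost_total,3406556743
ESSA,hly_undiscounted,36378783
ESSA,hly_discounted,4938728
ESSA,programme_acer,93.64
ESSA,share_cervical,45
ESSA,share_breast,48
ESSA,share_colorectal,7
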