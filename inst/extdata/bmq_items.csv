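scale,item_id,reverse,scale_min,scale_max
specific_necessity,SN1,TRUE,5,25
specific_necessity,SN2,TRUE,5,25
specific_necessity,SN3,TRUE,5,25
specific_necessity,SN4,TRUE,5,25
specific_necessity,SN5,TRUE,5,25
specific_concerns,SC1,TRUE,5,25
specific_concerns,SC2,TRUE,5,25
specific_concerns,SC3,TRUE,5,25
specific_concerns,SC4,TRUE,5,25
specific_concerns,SC5,TRUE,5,25
general_overprescribing,GO1,TRUE,4,20
general_overprescribing,GO2,TRUE,4,20
general_overprescribing,GO3,TRUE,4,20
general_overprescribing,GO4,TRUE,4,20
general_prejudices,GP1,TRUE,4,20
general_prejudices,GP2,TRUE,4,20
general_prejudices,GP3,TRUE,4,20
general_prejudices,GP4,TRUE,4,20
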