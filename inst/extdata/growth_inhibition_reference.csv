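setting,schedule,day,percent_gi
invitro_chip,mono,7,52
invitro_chip,combo_gap24,7,88
invitro_chip,combo_gap72,7,70
invivo_xenograft,mono,15,53
invivo_xenograft,combo_gap24,15,69
invivo_xenograft,combo_gap72,15,46
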