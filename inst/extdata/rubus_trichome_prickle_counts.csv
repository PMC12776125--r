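trichome_rating,smooth,bristles,prickles,prickles_and_bristles
hairy,42,6,0,0
short_glandular,17,17,132,17
short_and_elongated_glandular_sparse,0,1,63,21
short_and_elongated_glandular_abundant,0,1,3,12
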