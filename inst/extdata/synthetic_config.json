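{"biomarkers":["hippocampus","csf_tau","fdg_pet","memory"],"event_levels":[[1,2,3],[1,2,3],[1,2,3],[1,2,3]],"z_max":[5,5,5,5],"sigma":[1,1,1,1]}
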