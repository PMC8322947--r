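subject_id,condition,angle_deg,ap_mmHg,hr_bpm,pne_pg_ml
GROUPMEAN,baseline,-7,91,96,83
GROUPMEAN,baseline,0,87,98,92
GROUPMEAN,baseline,15,79,100,129
GROUPMEAN,baseline,60,59,118,278
GROUPMEAN,blockade,0,61,89,47
GROUPMEAN,blockade,15,46,86,40
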