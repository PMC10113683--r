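patient,sex,age_y,location,stage,gtv_volume_cm3,gtv_mean_hu,motion_range_mm,n_markers
1,M,86,right middle lobe,cT1bN0M0,7.0,-176.2,22,3
2,M,88,right middle lobe,cT1bN0M0,11.6,-260.0,28,4
3,F,90,left lower lobe,cT1aN0M0,5.1,-145.7,13,4
4,M,82,left upper lobe,cT1bN0M0,6.0,-203.9,25,3
5,F,83,left lower lobe,cT1bN0M0,15.8,-340.0,22,2
6,M,71,right lower lobe,cT1bN0M0,7.9,-329.6,26,4
7,M,81,right upper lobe,cT1bN0M0,2.8,-249.7,11,5
8,M,79,right lower lobe,cT2aN0M0,25.7,-19.8,25,4
9,M,79,right lower lobe,metastasis,1.2,-346.0,13,5
10,F,71,right lower lobe,cT1cN0M0,17.8,-37.7,17,4
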