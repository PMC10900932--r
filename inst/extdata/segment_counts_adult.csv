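number,site,n_segments
1,skull,1
2,cervical_vertebra,3
3,thoracic_vertebra,5
4,lumbar_vertebra,5
5,sternum,2
6,pelvic_bones,8
7,sacrum,10
8,proximal_femora,2
9,proximal_humeri,1
10,scapulae,3
11,clavicles,3
12,ribs,4
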