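component,source,size_class,delta_pct,classification
shape_stylization,TBV,TBV1,0,shared
shape_stylization,TBV,TBV2,15,shared
shape_stylization,TBV,TBV3,13,shared
shape_stylization,TBV,TBV4,7,shared
shape_stylization,CBV,CBV1,0,shared
shape_stylization,CBV,CBV2,15,shared
shape_stylization,CBV,CBV3,10,shared
shape_stylization,CBV,CBV4,14,shared
shape_stylization,CBV,CBV5,9,shared
shape_stylization,CBV,CBV6,4,shared
voxelization,any,any,1,shared
model_restriction,TBV,small,5,shared
model_restriction,TBV,large,0,shared
model_restriction,CBV,any,0,shared
cortical_uniformity,TBV,any,0,shared
cortical_uniformity,CBV,any,7,shared
microarchitecture_variability,any,any,20,unshared
chemical_composition,any,any,4,unshared
bone_density,TBV,large,4,unshared
bone_density,TBV,small,6,unshared
bone_density,CBV,large,0,unshared
bone_density,CBV,small,13,unshared
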