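acronym,full_name,excluded_by_voxel_threshold,excluded_in_some_models
AUDd,Dorsal auditory area,FALSE,FALSE
CA3,"Hippocampus, field CA3",FALSE,FALSE
DG,"Hippocampus, dentate gyrus",FALSE,FALSE
PTLp,Posterior parietal association areas,TRUE,FALSE
RSPagl,"Retrosplenial area, lateral agranular part",TRUE,FALSE
RSPd,"Retrosplenial area, dorsal part",TRUE,FALSE
SSp-bfd,"Primary somatosensory area, barrel field",FALSE,FALSE
SSp-tr,"Primary somatosensory area, trunk",FALSE,FALSE
SSs,Supplemental somatosensory area,FALSE,FALSE
VISal,Anterolateral visual area,TRUE,FALSE
VISam,Anteromedial visual area,TRUE,FALSE
VISl,Lateral visual area,FALSE,TRUE
VISp,Primary visual area,FALSE,FALSE
VISpm,Posteromedial visual area,FALSE,FALSE
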