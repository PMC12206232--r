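level,label,gene,parent
major,leukocyte,PTPRC,
major,endothelial,CDH5,
major,epithelial,EPCAM,
major,fibroblast,PDGFRA,
major,smooth_muscle,ACTA2,
lineage,macrophage,CD68,leukocyte
lineage,monocyte,CSF1R,leukocyte
lineage,neutrophil,CSF3R,leukocyte
lineage,T_cell,CD3G,leukocyte
lineage,B_cell,CD79A,leukocyte
lineage,NK_cell,NCAM1,leukocyte
lineage,dendritic,CD80,leukocyte
subtype,M1,IL1B,macrophage
subtype,M2,MRC1,macrophage
subtype,M2a,FN1,macrophage
subtype,M2a,TGM2,macrophage
subtype,M2b,IL1B,macrophage
subtype,M2c,MERTK,macrophage
subtype,M2d,VEGFA,macrophage
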