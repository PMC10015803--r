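salon_id,worker_id,duration_min,chemical,cas,chem_class,concentration
panelmax,max,176,1-Methoxy-2-propanol,107-98-2,VOC,18
panelmax,max,176,2-Buthoxyethanol,111-76-2,VOC,10
panelmax,max,176,2-Butoxyethylacetate,112-07-2,VOC,7
panelmax,max,176,2-Ethylhexanol,104-76-7,VOC,220
panelmax,max,176,2-Phenoxyethanol,122-99-6,VOC,19
panelmax,max,176,"2,4-Toluene diisocyanate",584-84-9,VOC,10
panelmax,max,176,"2,6-Toluene diisocyanate",91-08-7,VOC,12
panelmax,max,176,Acetaldehyde,75-07-0,aldehyde,30
panelmax,max,176,Acetone,67-64-1,VOC,170
panelmax,max,176,a-pinene,80-56-8,VOC,14
panelmax,max,176,Decanal,112-31-2,aldehyde,22
panelmax,max,176,Decane,124-18-5,VOC,10
panelmax,max,176,Dihydromyrcenol,18479-58-8,VOC,20
panelmax,max,176,Dodecanol,112-53-8,VOC,87
panelmax,max,176,Formaldehyde,59-00-0,aldehyde,38
panelmax,max,176,Hedione,24851-98-7; 2630-39-9,VOC,57
panelmax,max,176,Hexadecanol,36653-82-4,VOC,180
panelmax,max,176,Isopropanol,67-63-0,VOC,58
panelmax,max,176,Limonene,5989-27-5,VOC,310
panelmax,max,176,MEK; 2-Butanone,78-93-3,VOC,6
panelmax,max,176,Nonane,111-84-2,VOC,<RL
panelmax,max,176,Nonanal,124-19-6,aldehyde,28
panelmax,max,176,Octanal,124-13-0,aldehyde,20
panelmax,max,176,Propylene glycol,57-55-6,VOC,65
panelmax,max,176,Siloxanes; silicones,14857-34-2,VOC,700
panelmax,max,176,Toluene,108-88-3,VOC,31
panelmax,max,176,Undecane,1120-21-4,VOC,10
panelmax,max,176,Xylene,95-47-6; 108-38-3; 106-42-3,VOC,<RL
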