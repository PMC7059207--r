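# cadmrmc_schema: 1
reader_id,n_positive,n_rejected,n_normal,n_benign,n_malignant,n_birads3,n_birads4,n_birads5
reader1,46,16,6,8,2,8,6,2
reader2,46,20,5,11,4,10,10,0
reader3,47,15,2,11,2,8,5,2
reader4,52,24,7,12,5,9,14,1
reader5,51,18,5,11,2,9,6,3
reader6,56,26,7,17,2,13,11,2
reader7,69,34,20,11,3,16,16,2
reader8,80,43,29,9,5,18,15,10
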