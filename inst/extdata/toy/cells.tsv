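cell_id	dataset_id	condition	batch
cell1	dataset1	unknown	batch1
cell2	dataset1	unknown	batch1
cell3	dataset1	unknown	batch1
cell4	dataset1	unknown	batch1
cell5	dataset1	unknown	batch1
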