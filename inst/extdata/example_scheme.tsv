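# Example label scheme: id  name  macro_region
# FreeSurfer-LUT-style files (extra colour columns) are also accepted.
0	unknown	other
1	precentral	cortical
2	postcentral	cortical
3	superior-frontal	cortical
4	lateral-occipital	cortical
35	thalamus	subcortical
36	caudate	subcortical
37	putamen	subcortical
38	hippocampus	subcortical
46	cerebral-white-matter	other
47	ventricles	other
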