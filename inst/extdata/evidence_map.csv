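evidence,itype,dialect
reconstituted complex,P,biogrid
pca,P,biogrid
co-crystal structure,P,biogrid
yeast-two-hybrid,P,biogrid
affinity capture,A,biogrid
biochemical activity,A,biogrid
co-fractionation,A,biogrid
co-purification,A,biogrid
far western,A,biogrid
biophysical,P,mint
protein complementation assay,P,mint
biochemical,A,mint
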