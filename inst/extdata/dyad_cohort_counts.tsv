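# Cohort-level event and annotation counts reported for the ten-dyad
# cohort. The activation-event count (12574) and the activated
# gene-family count used in the annotation comparison (12564) differ by
# ten in the source counts; both are carried here unmodified.
quantity	value
shared_strains_total	51
shared_strains_with_transcriptome_signal	21
gene_family_universe	68850
activation_events	12574
deactivation_events	14844
activated_gene_families	12564
activated_unannotated	5764
deactivated_gene_families	14844
deactivated_unannotated	9935
all_unannotated	37156
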