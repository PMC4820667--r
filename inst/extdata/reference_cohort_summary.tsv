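key	value
discovery_n	265
discovery_srs1_n	108
discovery_srs2_n	157
validation_n	106
validation_srs1_n	37
validation_srs2_n	69
probes_measured	26185
top_variable_fraction	0.10
de_called	3080
de_down_srs1	2260
mort14_discovery_deaths	40
mort14_srs1_deaths	24
mort14_srs2_deaths	16
sofa_mean_srs1	7.9
sofa_sd_srs1	4.0
sofa_mean_srs2	5.4
sofa_sd_srs2	3.2
signature_genes_defined	398
signature_genes_measured	331
eqtl_samples	240
eqtl_snps_tested	644390
eqtl_probes_tested	17347
hazard_ratio_discovery	2.4
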