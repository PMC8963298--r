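feature_id	is_xenobiotic	is_derived	pathway
met_01	FALSE	FALSE	NA
met_02	FALSE	FALSE	NA
met_03	FALSE	FALSE	NA
met_04	FALSE	FALSE	NA
met_05	FALSE	FALSE	NA
met_06	FALSE	FALSE	NA
met_07	FALSE	FALSE	NA
met_08	FALSE	FALSE	NA
met_09	FALSE	FALSE	NA
met_10	FALSE	FALSE	NA
met_11	FALSE	FALSE	NA
met_12	FALSE	FALSE	NA
met_13	FALSE	FALSE	NA
met_14	FALSE	FALSE	NA
met_15	FALSE	FALSE	NA
met_16	FALSE	FALSE	NA
xeno_01	TRUE	FALSE	NA
xeno_02	TRUE	FALSE	NA
ratio_01	FALSE	TRUE	NA
ratio_02	FALSE	TRUE	NA
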