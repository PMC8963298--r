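# metabscreen parameter file
project_name=synthetic fixture
platform=synthetic
data_file=abundance.tsv
sample_metadata_file=sample_metadata.tsv
feature_annotation_file=feature_annotation.tsv
batch_normalization_column=batch
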