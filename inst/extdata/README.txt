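Reference raw-data CSVs (reference_rating_fdse.csv, reference_oq_windows.csv)
are not redistributable and must be supplied locally; see
tests/testthat/test-acceptance.R for the expected columns.
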