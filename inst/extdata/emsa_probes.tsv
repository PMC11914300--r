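name	sequence
RPL10	ACCCCCUGCACACUUACCCAAUCCUUUUAG
eIF5A	AUCUCUUGGCUAUCCCUCUUGCUUCUCCAG
TRAF4	ACUCCUGCCUCUCUACUUCUGUGGCCCCAG
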