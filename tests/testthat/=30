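Error in parse_filter(cr) : cannot parse filter expression: 'age'
Calls: load_filtered ... apply_filters -> lapply -> FUN -> parse_filter -> stop_survmeta
In addition: Warning message:
In bitwXor(h, b) : NAs introduced by coercion to integer range
Execution halted
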