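Causation
Cause_to_start
Cause_to_end
Cause_change
Reason
Response
Trigger
Means
Consequence
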