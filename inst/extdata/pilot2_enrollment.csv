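quantity,value,provenance
n_consented,296,published pilot-2 enrollment flow
n_declined,8,published pilot-2 enrollment flow
n_analyzed,288,published pilot-2 enrollment flow
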