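variable,events_low,n_low,events_high,n_high,provenance
women,40,60,43,69,published pilot-1 summary (construct-validity cohort; N=129)
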