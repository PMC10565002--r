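variable,events_low,n_low,events_high,n_high,provenance
women,67,129,80,159,published pilot-2 summary (criterion-validity cohort; N=288)
one_on_one,7,129,23,159,published pilot-2 summary (criterion-validity cohort; N=288)
readmit_30d,19,129,26,159,published pilot-2 summary (criterion-validity cohort; N=288)
mortality,4,129,10,159,published pilot-2 summary (criterion-validity cohort; N=288)
discharge_nh,10,129,42,159,published pilot-2 summary (criterion-validity cohort; N=288)
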