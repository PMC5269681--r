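# Published mean first passage times for the thymine-dimer flipping
# reaction, intra- to extra-helical (tau+) and back (tau-).
# columns: system tau_forward_s tau_backward_s
CPD_BDNA 3.8e1 1.7e-6
TT_BDNA 2.0e1 4.6e-7
CPD_1TEZ 4.5e-3 1.9e-7
TT_1TEZ 1.6e-1 5.2e-7
CPD_prot 1.2e-4 1.7e-2
TT_prot 3.9e-3 3.7e-3
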