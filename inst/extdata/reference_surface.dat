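# surface Calpha-Calpha distances (nm), R = 7
0.380766175073 0.659281474839 0.924355314224 1.221543632425 1.400613269994 1.470822966809 0.380766175073 0.659281474839 0.929340192562 1.052285065525 1.136246899103 0.380766175073 0.575887748831 0.758561589276 0.870935984024 0.380766175073 0.659281474839 0.924355314224 0.380766175073 0.659281474839 0.380766175073
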