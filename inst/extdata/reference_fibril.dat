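# fibril Calpha-Calpha distances (nm), R = 7
0.380766175073 0.693492155723 1.052042215422 1.386984301295 1.740808078229 2.080476426581 0.380766175073 0.693492155723 1.052042215422 1.386984301295 1.740808078229 0.380766175073 0.693492155723 1.052042215422 1.386984301295 0.380766175073 0.693492155723 1.052042215422 0.380766175073 0.693492155723 0.380766175073
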