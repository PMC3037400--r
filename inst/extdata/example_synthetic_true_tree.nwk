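(t5:0.08535219043,t2:0.1143065593,((t8:0.1205552965,(t4:0.01627821051,(t1:0.2799837856,t9:0.0137785146):0.009724177542):0.4194613255):0.1068668348,(t3:0.04077172399,(t10:0.05999642628,(t6:0.01633422387,t7:0.145977434):0.2304325145):0.07603557305):0.06712387266):0.1496313423);
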