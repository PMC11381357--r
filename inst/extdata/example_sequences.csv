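id,invader,substrate,incumbent,toehold_len
sys001,CGTCTATCATTCAATACCCTAC,GTAGGGTATTGAATGATAGACG,GTAGGGTATTGAATGA,6
sys002,GCCGTTTCATTCAATACCCTAC,GTAGGGTATTGAATGAAACGGC,GTAGGGTATTGAATGA,6
sys003,ACAGCGTCATTCAATACCCTAC,GTAGGGTATTGAATGACGCTGT,GTAGGGTATTGAATGA,6
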