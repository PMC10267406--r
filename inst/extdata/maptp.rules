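# Tau phosphorylation switch: the kinase complex drives MAPT
# phosphorylation, the prolyl isomerase opposes it.
CDK5_p25, CDK5_p25
PIN1, PIN1
MAPTP, CDK5_p25 & !PIN1
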