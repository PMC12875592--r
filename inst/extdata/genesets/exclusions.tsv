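gene	reason
HK1	hexokinase catalyzes the first step of both glycolysis and the pentose phosphate pathway
HK2	hexokinase catalyzes the first step of both glycolysis and the pentose phosphate pathway
HK3	hexokinase catalyzes the first step of both glycolysis and the pentose phosphate pathway
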