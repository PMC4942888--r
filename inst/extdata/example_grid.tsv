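# worked example: one implicative dilemma (generous/depressed vs selfish/happy)
scale 1 7
SELF:Self	IDEAL:Ideal	Mother	Father	Friend
generous	2	1	2	6	5	selfish
depressed	2	7	1	6	6	happy
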