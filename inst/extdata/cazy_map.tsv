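ko_id	family
K01011	GH2
K01012	GH13
K01013	GH20
K01014	GH29
K01015	GH33
K01016	GH95
K01017	GH16
K01018	GH3
K02021	GT2
K02022	GT4
K02023	GT51
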