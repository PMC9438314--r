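pathway_id	ko_id
glycan_degradation	K01011
glycan_degradation	K01012
glycan_degradation	K01013
glycan_degradation	K01014
glycan_degradation	K01015
glycan_degradation	K01016
glycan_degradation	K01017
glycan_degradation	K01018
glycan_degradation	K01019
glycan_degradation	K01020
ribosome	K02021
ribosome	K02022
ribosome	K02023
ribosome	K02024
ribosome	K02025
ribosome	K02026
ribosome	K02027
ribosome	K02028
ribosome	K02029
ribosome	K02030
galactose_metabolism	K01031
galactose_metabolism	K01032
galactose_metabolism	K01033
galactose_metabolism	K01034
galactose_metabolism	K01035
galactose_metabolism	K01036
galactose_metabolism	K01037
galactose_metabolism	K01038
galactose_metabolism	K01039
galactose_metabolism	K01040
oxidative_phosphorylation	K02041
oxidative_phosphorylation	K02042
oxidative_phosphorylation	K02043
oxidative_phosphorylation	K02044
oxidative_phosphorylation	K02045
oxidative_phosphorylation	K02046
oxidative_phosphorylation	K02047
oxidative_phosphorylation	K02048
oxidative_phosphorylation	K02049
oxidative_phosphorylation	K02050
pts_system	K01051
pts_system	K01052
pts_system	K01053
pts_system	K01054
pts_system	K01055
pts_system	K01056
pts_system	K01057
pts_system	K01058
pts_system	K01059
pts_system	K01060
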