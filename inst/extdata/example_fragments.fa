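>pos_0001
LLVYIKVAVVTLALGLEINTANNLFGKISVVVIWGYPAYI
>pos_0002
YNKFMTFMAVVAIVGTSGSAAIAIFPFLFAAFRQQNTIAN
>pos_0003
VMFGIPVAGGAFIDLTVSALMFFFTVPGNGQSNTVFLWTT
>neg_0001
NYTYSGVGVMVCLKLNVVIYATHYFWGSGGIYVAITIMIM
>neg_0002
LGMEDIVCMMFLYVIMWMLAINAISQMAAWLLFALAPGWI
>neg_0003
YMGIISSMMVMVVNRKLAWAPLFGLLRMTAAMTIRLSMGI
>neg_0004
LSWAIVYIYIFGQGVMSAPRFAPILPVAFLFVSIAAVISM
>neg_0005
FVLILASVQALAMSFITLNIGAILECHGQTAASLIVWLSA
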