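>beta_casein synthetic stand-in for bovine beta-casein; VLPVPQKAVPYPQR at 185-198
MGGSENSELDALRTPEVDDEALDKVGLNAQSAPLRLDAQSAPLGGFGKEVDDEALEKNQD
TEGGLFRSSDELNFLKGVDASLLGGKTDLEGNQFRAPSFSDIPNPIRGLDVQASELDTKN
ENSGELTDFAKGGSENSELDALRTPEVDDEALDKVGLNAQSAPLRLDAQSAPLGGFGKEV
DDERVLPVPQKAVPYPQR
>as1_casein synthetic stand-in for bovine alpha-s1-casein; contains HQGLPQEVLNENLLR
MEVDDEALEKTDLEGNQFRKHQGLPQEVLNENLLRFVGLNAQSAPLRSSDELNFLK
>beta_LG synthetic stand-in for bovine beta-lactoglobulin; contains ALPMHIR
MTPEVDDEALDKNQDTEGGLFRKALPMHIRLGVDASLLGGKNENSGELTDFAK
>as2_casein synthetic stand-in for bovine alpha-s2-casein
MLDAQSAPLGGFGKAPSFSDIPNPIRGGSENSELDALR
>kappa_casein synthetic stand-in for bovine kappa-casein
MGLDVQASELDTKEVDDEALEKTDLEGNQFR
>alpha_LA synthetic stand-in for bovine alpha-lactalbumin
MNENSGELTDFAKVGLNAQSAPLRTPEVDDEALDK
>BSA synthetic stand-in for bovine serum albumin
MSSDELNFLKNQDTEGGLFRAPSFSDIPNPIRGVDASLLGGK
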