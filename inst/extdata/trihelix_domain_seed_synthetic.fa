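>seed1 synthetic trihelix-like domain seed (not a database-derived alignment)
MEWTPEQNKLFENALAVYDKDTPDRWQKVARAVGGKTVEEVKRHYELLVEDV
>seed2
MDWTPEQNRLFENALAVYDKETPDRWAKVARMVGGKTAEEVKRHYELLVEDI
>seed3
MEWSPEQNKLFESALAVYDKDTPDRWQKVAAAVGGKSVEEVKRHYEILVEDV
>seed4
MEWTPEQNKLFERALAIYDKDTPDRWQNVARAVGGRTVEEVKRHYELLVDDV
>seed5
LEWTPEQNKLFENALAVYPKDTPDRWQKVARAVGGKTVEEVQRHYELLVEDV
>seed6
MEWTPEQNKLFENALATYDKDTLDRWQKVARAVEGKTVEEVKRHYELLVEDV
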