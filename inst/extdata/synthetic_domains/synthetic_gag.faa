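>tf_like_consensus
AKIEPFHRNRNSHGVCWSTWKRDLFSYCGEHGSKTQCYNMLVEMIHNAGNAINMNKMINTWQIAYIRLWP
MWHSEMSVTCHRPEPLRAPY
>tf_like_var1
AKIEPFHRNRNLPGVCWSTWKRDLFSYCGVHGGKTQCYNMLVEMIHNAGNNIIMNKMINTWTIAYIRPWP
MLHSEMSVTCHRPEPLRAPF
>tf_like_var2
SKIEPFHRVRNSHGVCWSTWKRDLFSYCGEHGSKTQCYNMLPEMQHQFGNAINMNKMINTWQIAYMRLWP
MWHSEMSVTCHRPEPLRAPY
>tf_like_var3
AKIEQFHRNRNGHFVCWSTWKRDLFSYCGEHGSKTQCYNMLVEMIHNAGNAINMNKMPNPWQIAYIRLWP
AWHSEGSVTCHFPEPLRAPY
>ty3_like_consensus
AKIASCAWNMNEHAVCLSDWQRDLFSYVGECGKKTQCYNHLNRMIYNAGNAIYQNKMINKWQQANIRLWM
GWHSEMVCGCWGVHPLQACY
>ty3_like_var1
AKIASCAWNMDEHAVCLSDWQRDLFSYVGECGKKTRCYNHLNRMIYNAGNAIYQNLMISKWQQANIRLWM
GWHSEMVCGCWGVHPLQACY
>ty3_like_var2
AKIASCAWNMCEHAVCLSDWQRSLFSYVGECGKKTCCYNHLNRMIENAGNAIYQNKMFNKAQQTNIILWM
GWHSEMVCGCWGVHPLMACY
>ty3_like_var3
AKIASCAWNMNEHAVCLSDWQRDLCSYVGECGKKTQCYNHLNPMIYNAGNAIYWNKMINKWQQANIRLWM
GWHSLMVCGCWGVHPLQACY
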