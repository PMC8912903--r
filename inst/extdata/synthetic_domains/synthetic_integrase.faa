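>tf_like_consensus
FTKNFKFDFRCEECGCRGTHYKQMWHIQAEKDSIKQWQVSMFVSPSVYDNTGHRQRPGNGSVFHVFGCDT
DDEPFVLHGKKCFTRRSLCNPWASFMGPMW
>tf_like_var1
FTKNFKFDFRCEECMCCGTHYKQMWHIQAEKDSIRQWQVSMFVSPSVYDNTGHRQRPGNGSVFHVFGCDT
DDEPFVLHVKKCFTRRSLCNPWASFTGPMW
>tf_like_var2
FTKWFKFDFRCEECGCGGTHYKQMWHIQAEKDSIKYWQVSMFGSPSVYDNTGHRQRPGNGSVFHVFGCDT
DDEPFVLHGKKCFTRRSLCNPWASFMGPMW
>tf_like_var3
FQTNFKFDFRCEEYGCRGTHYKQMWDIQAEKDSIKQWQVSMFVSNSVYDNTGHRQRPGNGSVFFVFGCNT
DDEPFVLHGKKCFTRRSGCNPWAQFMGPMQ
>ty3_like_consensus
FKKNFYFDFREEFKGCRGTHYKMMWHIWAEFLSIKQWLKSMTVNCSVYDNTTHLQRPGNGSFFHVERCDT
EMRKFVLEGHNDFTRISLQKLEAFPMGADS
>ty3_like_var1
FKKNFYFDFREEFKDCRGTHYKFMWHIWAEFLSMKQWLKSMTVNCSWYDNTTHLQRPGNGSFFHAERCDT
EMRKAVLTGHNDFTRISLQKLEAFPMGADS
>ty3_like_var2
FKKNFYFDFREEFKGCRGTHYKMMWHIWAEFLSIKQWLKSATVNCSVYMNTVHLQRYGNGSFFNVEVCQV
EMRKGVLEGHNDFTRISLQKLTAFPMGADS
>ty3_like_var3
FKKNNYFDFREEFKGCRGTHYKMMWHIWALFLSIKQWLKSMTVNDSVYPNTTHLQRPGNGLFWHVERCDT
EMRKFVLEGINDFTRISLQKLEAFPMGADS
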