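>tf_like_consensus
KILWQDYEPMGPSVQAREAISCWSTCLKRAPTMGDFEINCASGYNPKRVGHEWECPVVDVHTFLWHGAMW
>tf_like_var1
KILWQDYEPMGASVQAREADSCWSTCLKRAPTMGDFEINMASGYKIKRVGHESECPVVDVHTFLWHEAMW
>tf_like_var2
DALWQDYEPMGPSVQAREAISCWSTRSKRAPTMGDFEFNCASHYNPKRVGHEWECPVVVVHDFLWHGAMW
>tf_like_var3
KIPWQDYIPMGPSVQTREAISCWSTCLKRAPTMGDFEINCASGYNPTRVGHEWECPQVDVHTFLWHGAVW
>ty3_like_consensus
KILMLIYENMWISNQALQAPSAWVTCLKRAPTMGDFQILWKSGYNLLRVGHDWECPVVDSHTFLWHGHMW
>ty3_like_var1
DILMLIYEYVWISNQALQAPWAWVTCLKRADTMGDFEILWKSGYNLLRVGHDWECPVVDSHTFLEHGHMW
>ty3_like_var2
KILRLIFENMPMSNQALQAPSAWVNCLKRAPTMGDFQILWKSGYNLLRVGHDWEPPVVDSHTFLWHGHMW
>ty3_like_var3
FILMLIYENMWISNQTLQAPAAWVTCLKRAPTMGDFQILWKSGYNLLKVGHDWECPVNDSHTFLWHYHMW
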