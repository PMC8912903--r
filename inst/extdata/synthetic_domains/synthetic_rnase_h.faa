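>tf_like_consensus
EYRFNRCRLPFMHAKDCEYYQMVYNRWFYHENGANNKQYNDAPCMNNCVILCNQDFGSCWYDQGMMKAIY
RFQLFHPQNW
>tf_like_var1
EYRFNRCRLPFMHAKDCEYYQMVDYRWFYHENGANNKQYNDAPCMNNCVILCNQYFGSCWYDQQMMKCIY
RYQLFHPQYW
>tf_like_var2
EYRFNRCRLPFMHAKDCEYYQMVYNRWFYHENGANNKQYNCAPCMNNCVIHCNQDQGSCWYDQGMMKAIF
EFMLFHPYNW
>tf_like_var3
EYRFNRLRLPFMHAKDCEYYQMVYNPWFMHENGANNKQYNDRPCMNWCVILYNQDFGSCWYDQGMMKAIY
RFQLFNPQDW
>ty3_like_consensus
EYWFIRTHLRFMQAKDCEYYQMVYNRWFLHENWAINKQYKAAPVCNNCVIGCFWYFGKCWNDQGMHMAIY
RDQHFHPQNW
>ty3_like_var1
ESWFIRTHLRFMQAKDCEYYQWVGNRWFLHENWAINTQYKAAPVCNETVIGCFWYFGKCWNDQGMHMAIY
RDQHFHPQNW
>ty3_like_var2
EYWFIRTHLRFMQPKDCEYYQMVYNRWFLHENWAINKRYKAAPVCNNCEIGCFWYFGKCWNDQGMHMAIY
RDQHFHPQNW
>ty3_like_var3
EYWFIRTHLRFMQAKDCEYYQMVYNRWFLHENWAINKQYKAAMCGNNCVIGCFMYFGKCWNDQGMHMAIY
RDGHFHPQNW
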