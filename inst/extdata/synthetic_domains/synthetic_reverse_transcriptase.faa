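>tf_like_consensus
YINWYYSQLACHYQWCLRRFAMNVVQIQMAEMHLVMEMKCRWFEFLTKYNSMRAALPWKAKGVCNEFYMK
TRKVQPHCHRQCFLRCNELRETTIWFADLPLKQKLIQADIKQGINFEEYM
>tf_like_var1
YINWYYSQCACHYQWCLRRFAMNVVQIQMAVMHLVMEMKCRWFEFLTKYNSMRRAHPWKAQGVCNEFYMK
TRKVQPHCHRQCFLRCNELRETTIIFADLPLKQKLIQADIKQGINFEEYM
>tf_like_var2
YINWYYSQLACHYQWCLRRFAANVVQIQMAEMHLVMEMKTNWFEFLTKYNSMRAALPWKAKGVCNEFYMK
TRKVQPHCHRQCFLGCEELRETTIWFADLPLKQKLIQADIKHGNNFEEYM
>tf_like_var3
YINWGYSHLACHYQWCLRRFAMNVVQIQMAEMHQVMEMKCRHFEFLTKYNSMRAALRWWAMGVCNRFYMK
TRKVVPHCHRQCFLRCNELRETTISFADLVLKQKYIQADIKQGINFEEYM
>ty3_like_consensus
YINLYYHQDRCHRGWCLLAFAMGVVQIQMAEMHLVMEMKCQWFEFLTKYNSMRAQLPCKAEGSCLEFYQK
TIKVQPHGHRMCFLRFNELREKIIWKAEGRKKQKSKQYDIRQGANFYEWM
>ty3_like_var1
YINLYYHQDRCHRGWCLGAFGMGVVQIQMARMHLVMEHKCQWFEFETFYNSMRAQDPCKAEGSCLEFYPK
TIKVQCHWHRMCFKRFNESREKAIWKAECRKKQYSKQYDIRQGANFYEWI
>ty3_like_var2
WINLYYHQDRCHRGWCLLAFAMYVVQIQMAEMHLRMEMKCQWFEFLTKYNSMRAQLPCKAEGSCLEFYQK
TIKVQPHGHRMCFLRFNELREKIIWKAESRKKQKSKVYDIRQGANFYEWM
>ty3_like_var3
YINLLYHQDRCHRGWCLLAFAMSVVTIQMSEMHLVMEMKCQWCEFLTKYNSMRAQLPCHAEGSCLEFYQK
TIKVQPHGHRMCFLRFNELREKIIWWAEGRKKSKSKQYDIRQGANLYMKM
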