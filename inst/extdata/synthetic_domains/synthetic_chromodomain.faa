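>tf_like_consensus
IYYVICPAKNLENCIPEKGLRANWHINWLHFQKHSHARQKMRAVKSEPQW
>tf_like_var1
IYYNICPPKNLENCSPEFGLRANWHINWLHFQKHSHARQKMRAVKSEPQW
>tf_like_var2
IYYVHCPAKKLENCIPEKGLRANWHINWAHFQKHSHARQKMRAVKSEPQW
>tf_like_var3
IYYVICPAKNLENCICEGGLRANWHINWLHFQKNSHTRQKMRAVKSEPQW
>ty3_like_consensus
SYYVDCWIWNLENNLPEKGLNANKNANYLQFQKYIPARQKMRHVGSERQW
>ty3_like_var1
SYYVDCWIWNLWNNLPEKGLNANKNANYLQFQKRIPARQKMRHVGSERQW
>ty3_like_var2
SYYVDCWIWNLEHALVEKGLYANKNANYLVFQKYIPARQKMRHVGSERQW
>ty3_like_var3
SYYPDCWIWNLEENLPEKGLNANKNANQLQFQKSIPMRQKVRHVGSERQW
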