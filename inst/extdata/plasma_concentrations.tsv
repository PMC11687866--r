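metabolite	concentration_uM
glucose	5000
alanine	430
glutamine	570
glycine	230
valine	220
lysine	180
leucine	120
threonine	140
serine	110
isoleucine	60
proline	240
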