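Item,A1,A2,A3,A4,A5,A6,A7,A8
Item1,0,0,0,0,0,1,0,0
Item2,0,0,0,0,0,1,0,0
Item3,0,0,0,0,0,1,0,0
Item4,0,0,0,0,1,0,1,0
Item5,1,1,0,0,0,0,1,0
Item6,1,1,0,0,1,0,1,0
Item7,0,0,0,0,1,1,1,0
Item8,0,0,0,0,0,1,1,0
Item9,1,0,0,0,0,1,1,0
Item10,1,0,0,0,0,1,0,0
Item11,0,0,0,1,1,0,1,0
Item12,0,0,0,1,0,0,1,1
Item13,1,1,0,0,0,1,0,0
Item14,0,0,0,0,1,1,1,0
Item15,0,0,0,0,0,0,1,1
Item16,0,0,1,0,0,0,0,0
Item17,0,0,1,1,0,0,0,0
Item18,0,0,1,0,0,0,0,0
Item19,0,0,1,0,0,0,0,0
Item20,0,0,1,1,0,0,0,0
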