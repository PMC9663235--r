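Question no.,Question,Answer no.,Answer,Next
1,Fear of cold?,A1,Fear of cold,2
,,A2,No fear of cold,2
2,Fever?,A3,Fever,3
,,A4,No fever,3
3,Does it last long or short?,A5,Long duration,Yang deficiency
,,A6,Short duration,Pattern of internal and external excess-cold
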