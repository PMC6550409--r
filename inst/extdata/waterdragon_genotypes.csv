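id,role,EWD69,Pcoc2,Pcoc6,Pcoc7,Pcoc9,Pcoc10,Pcoc13
WD-10,mother,304/316,212/224,200/204,162/170,312/324,212/236,222/234
WD-1,offspring,316,212,204,170,312,212,222
WD-2,offspring,316,224,200,162,312,236,222
WD-3,offspring,316,212,200,162,324,236,234
WD-4,offspring,316,224,200,170,324,212,234
WD-5,offspring,304,224,200,,324,212,234
WD-6,offspring,304,212,200,170,312,212,222
WD-7,offspring,316,224,200,170,324,212,234
WD-8,offspring,316,212,200,162,324,212,234
WD-11,offspring,316,212,200,170,324,212,222
106643,reference,338,187,204,162/170,300/308,226,174/178
141239,reference,328,200/208,196/208,154/178,320/332,222/230,178/182
192724,reference,312/320,216/220,174/182,170/174,288/296,212/232,178/206
192902,reference,304/308,200/210,200/202,158/170,292/312,222,216/220
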