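"time","ankle_x","ankle_y","hip_x","hip_y","torso_x","torso_y"
0,0,0,0.0898500749821453,0.895503748750223,0.188811658683955,1.28306871743448
0.05,0,0,0.087036246494197,0.895781609431786,0.184280655266165,1.28378099726969
0.1,0,0,0.0787667008071364,0.896546600486533,0.170909340475451,1.28578911352301
0.15,0,0,0.065549086333517,0.897609780071965,0.149356281875011,1.28873169709461
0.2,0,0,0.0482013386474573,0.898708312497772,0.120695360024788,1.29208423558476
0.25,0,0,0.0278071034304982,0.899570322431107,0.0863743206692321,1.29525944417305
0.3,0,0,0.00565110962356132,0.899982258136249,0.0481486794458294,1.29771829693485
0.35,0,0,-0.0168633314369617,0.899842001716328,0.00798963887688164,1.29906916745856
0.4,0,0,-0.0383085589885561,0.899184327214515,-0.0320297649084898,1.29913504510973
0.45,0,0,-0.0573293182705681,0.898172226951286,-0.0698605909078746,1.29797588777256
0.5,0,0,-0.0727321292077028,0.897056317842372,-0.103603099798552,1.29586326759974
0.55,0,0,-0.083559369255079,0.896112622280087,-0.131618353842339,1.29321504483684
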