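river,section,length_km,count,source
Li River,Xieshui,47,27,survey 2010-2012
Yuan River,Youshui,30,12,survey 2010-2012
Yuan River,Taoyuan,99,42,survey 2010-2012
Xiu River,Upper reach,71,43,survey 2010-2012
Xiu River,Middle reach,63,32,published count
Fu River,Yihuang,65,31,published count
Xin River,Luxihe,43,23,survey 2010-2012
Rao River,Leanhe,57,31,published count
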