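name,easting,northing,nitrate_spring,nitrate_autumn,nitrite_spring,nitrite_autumn
Dar asb,697952,3987484,48.00,42.00,0.01,0.02
Bash ghshlagh,683947,3999916,25.00,18.00,0.02,0.02
Darband,700662,3977609,20.20,13.20,0.02,0.04
Dalan,699013,3973730,16.00,12.10,0.03,0.03
Kalhor abad,688215,3947622,29.00,19.00,0.03,0.05
Bayz yadabad,668997,4016853,22.00,18.00,0.05,0.04
Ghleh reyhaneh,674959,3975291,25.00,11.60,0.05,0.05
Ahmad kar,670886,3995782,32.10,23.80,0.04,0.06
Shja abbad,674470,3963890,30.00,24.00,0.04,0.06
Ziki big alai,673237,4008669,29.00,24.10,ND,0.05
Sarab gherh khan,711010,3997938,31.90,23.00,0.05,0.06
Ebrahim abbad,665115,3982711,35.50,34.40,0.05,0.06
Kani shirin,681921,4013914,40.40,34.40,0.05,0.06
Ghleh kohneh,696522,4002364,48.00,45.00,0.05,0.07
Katak,674447,3981147,37.20,31.00,0.06,0.06
Kani shirn,682341,4014723,64.20,17.50,0.04,0.08
Kani chayi,679868,3997723,49.40,46.00,0.06,0.07
Goomehi,666685,4002175,37.00,35.50,0.06,0.08
Gadmeh getter,708022,3995250,57.00,51.00,0.07,0.07
Heydar dideh ban,686465,4004294,60.00,53.00,0.07,0.08
Ghaleh rootelh,681598,3990604,57.00,74.00,0.08,0.07
Shaali shel,683994,4005054,6.00,43.00,0.07,0.10
Radhid abbad,684050,3981000,40.00,14.30,0.09,0.09
Bardeh resheh,667004,4007168,24.10,22.00,0.09,0.10
Kalkan,673339,3987921,40.00,25.00,0.10,0.10
Seyer ali,676654,4002938,36.00,32.00,0.06,0.15
Tazeh abbad vazir,701701,3985774,29.00,18.50,0.12,0.14
Khaki big,672222,4005422,42.00,33.00,0.10,0.18
Youz bashi kenedi,670320,4019397,18.00,16.00,0.14,0.16
Ali abbad kerfeto,663074,4015530,50.00,34.40,0.12,0.20
Jiran mango,667248,3997466,38.40,33.10,0.03,0.30
Ghebi soor,687867,3967563,35.00,25.42,0.12,0.22
Seyr sofla,679204,4002392,31.00,24.00,0.19,0.20
Alijan,651667,3976515,51.00,45.00,0.10,0.34
Tazeh abbad maran,682562,4016289,38.00,30.80,0.30,0.30
Maran alia,677106,4010170,30.14,19.00,0.10,0.80
Abb barik,702412,3998803,40.00,38.00,0.09,1.00
Zafar abbad,678180,3988511,29.10,27.00,0.60,0.60
Ghar agol,699875,4000211,36.30,25.10,0.18,1.40
Zaki big sofla,675670,4006131,28.00,19.80,0.81,0.84
Ali abbad maran,673493,4015657,26.00,16.00,1.60,0.30
Morad ghloi,711662,3992611,45.00,39.00,1.00,1.30
Gol tapeh alia,669618,3999376,21.00,21.30,1.00,1.40
Papaleh,694851,4003853,68.80,48.80,1.20,1.50
Kas nzan,677961,3994592,26.00,19.00,1.20,1.60
Ghjan,680603,4007129,21.00,26.90,0.10,3.00
Hossen abbad maran,671410,4012546,123.00,63.50,1.40,2.00
Sharif abbad,659098,3977126,36.00,23.00,1.90,2.40
Gorr baba ali,667920,4011063,134.00,77.00,5.00,0.80
Darvishan,658642,3953591,26.00,23.00,3.00,3.20
Sar ghaleh,691282,3978327,28.60,19.50,3.00,3.60
Aghbelagh,692336,3953816,8.40,8.50,3.00,3.80
Kos anbar,659053,3946900,4.00,3.00,4.30,4.50
Tarz abbad ghazi ali,655032,3942337,0.90,1.30,5.00,4.40
Darvyan farsi,650015,3948737,5.00,3.00,5.00,5.30
Vazman,644630,3978902,5.40,4.80,5.60,6.00
Hezar kanian,663786,3959608,18.10,15.60,ND,ND
Tazeh abbad baharestan,694606,3946783,10.00,6.25,ND,ND
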