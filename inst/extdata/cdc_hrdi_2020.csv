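province,region,category,pop_density,area_density,hrdi,rank
Shanghai,Eastern,healthcare_technical,0.0901,0.3557,0.1790,1
Beijing,Eastern,healthcare_technical,0.1412,0.1840,0.1612,2
Tianjin,Eastern,healthcare_technical,0.1157,0.1419,0.1281,3
Jiangsu,Eastern,healthcare_technical,0.0927,0.0765,0.0842,4
Shandong,Eastern,healthcare_technical,0.0871,0.0575,0.0708,6
Hainan,Eastern,healthcare_technical,0.1201,0.0356,0.0654,7
Zhejiang,Eastern,healthcare_technical,0.0738,0.0467,0.0588,9
Fujian,Eastern,healthcare_technical,0.0970,0.0332,0.0568,14
Guangdong,Eastern,healthcare_technical,0.0644,0.0451,0.0539,15
Liaoning,Eastern,healthcare_technical,0.0931,0.0272,0.0503,18
Hebei,Eastern,healthcare_technical,0.0764,0.0304,0.0481,21
Henan,Central,healthcare_technical,0.0958,0.0570,0.0739,5
Hubei,Central,healthcare_technical,0.1093,0.0339,0.0609,8
Hunan,Central,healthcare_technical,0.1049,0.0329,0.0587,10
Jiangxi,Central,healthcare_technical,0.0988,0.0267,0.0514,17
Jilin,Central,healthcare_technical,0.1362,0.0175,0.0488,20
Shanxi,Central,healthcare_technical,0.0968,0.0216,0.0457,22
Anhui,Central,healthcare_technical,0.0676,0.0295,0.0447,23
Heilongjiang,Central,healthcare_technical,0.1334,0.0093,0.0353,26
Shaanxi,Western,healthcare_technical,0.1328,0.0255,0.0582,11
Yunnan,Western,healthcare_technical,0.1640,0.0202,0.0576,12
Guangxi,Western,healthcare_technical,0.1247,0.0265,0.0575,13
Guizhou,Western,healthcare_technical,0.1129,0.0247,0.0529,16
Sichuan,Western,healthcare_technical,0.1195,0.0208,0.0498,19
Ningxia,Western,healthcare_technical,0.1306,0.0142,0.0430,24
Chongqing,Western,healthcare_technical,0.0683,0.0266,0.0426,25
Gansu,Western,healthcare_technical,0.1321,0.0073,0.0310,27
Inner Mongolia,Western,healthcare_technical,0.1897,0.0039,0.0270,28
Xinjiang,Western,healthcare_technical,0.1769,0.0028,0.0221,29
Qinghai,Western,healthcare_technical,0.2073,0.0017,0.0188,30
Tibet,Western,healthcare_technical,0.3045,0.0009,0.0166,31
Shanghai,Eastern,other_technical,0.0182,0.0717,0.0361,1
Beijing,Eastern,other_technical,0.0112,0.0146,0.0128,5
Tianjin,Eastern,other_technical,0.0149,0.0183,0.0165,2
Jiangsu,Eastern,other_technical,0.0142,0.0118,0.0129,4
Shandong,Eastern,other_technical,0.0111,0.0073,0.0090,7
Hainan,Eastern,other_technical,0.0116,0.0034,0.0063,11
Zhejiang,Eastern,other_technical,0.0090,0.0057,0.0071,8
Fujian,Eastern,other_technical,0.0116,0.0040,0.0068,10
Guangdong,Eastern,other_technical,0.0074,0.0052,0.0062,14
Liaoning,Eastern,other_technical,0.0115,0.0034,0.0062,13
Hebei,Eastern,other_technical,0.0143,0.0057,0.0090,6
Henan,Central,other_technical,0.0200,0.0119,0.0155,3
Hubei,Central,other_technical,0.0124,0.0039,0.0069,9
Hunan,Central,other_technical,0.0112,0.0035,0.0063,12
Jiangxi,Central,other_technical,0.0064,0.0017,0.0033,23
Jilin,Central,other_technical,0.0169,0.0022,0.0061,15
Shanxi,Central,other_technical,0.0104,0.0023,0.0049,20
Anhui,Central,other_technical,0.0062,0.0027,0.0041,22
Heilongjiang,Central,other_technical,0.0189,0.0013,0.0050,18
Shaanxi,Western,other_technical,0.0055,0.0011,0.0024,27
Yunnan,Western,other_technical,0.0133,0.0016,0.0047,21
Guangxi,Western,other_technical,0.0115,0.0024,0.0053,17
Guizhou,Western,other_technical,0.0059,0.0013,0.0028,25
Sichuan,Western,other_technical,0.0140,0.0024,0.0058,16
Ningxia,Western,other_technical,0.0089,0.0010,0.0029,24
Chongqing,Western,other_technical,0.0079,0.0031,0.0049,19
Gansu,Western,other_technical,0.0098,0.0005,0.0023,28
Inner Mongolia,Western,other_technical,0.0190,0.0004,0.0027,26
Xinjiang,Western,other_technical,0.0144,0.0002,0.0018,30
Qinghai,Western,other_technical,0.0204,0.0002,0.0018,29
Tibet,Western,other_technical,0.0189,0.0001,0.0010,31
Shanghai,Eastern,managerial,0.0054,0.0214,0.0108,4
Beijing,Eastern,managerial,0.0101,0.0132,0.0116,2
Tianjin,Eastern,managerial,0.0154,0.0188,0.0170,1
Jiangsu,Eastern,managerial,0.0053,0.0044,0.0048,15
Shandong,Eastern,managerial,0.0085,0.0056,0.0069,10
Hainan,Eastern,managerial,0.0122,0.0036,0.0066,11
Zhejiang,Eastern,managerial,0.0038,0.0024,0.0030,25
Fujian,Eastern,managerial,0.0061,0.0021,0.0036,21
Guangdong,Eastern,managerial,0.0050,0.0035,0.0041,19
Liaoning,Eastern,managerial,0.0177,0.0052,0.0096,5
Hebei,Eastern,managerial,0.0076,0.0030,0.0048,14
Henan,Central,managerial,0.0146,0.0087,0.0113,3
Hubei,Central,managerial,0.0073,0.0023,0.0041,20
Hunan,Central,managerial,0.0096,0.0030,0.0054,13
Jiangxi,Central,managerial,0.0063,0.0017,0.0033,23
Jilin,Central,managerial,0.0216,0.0028,0.0077,7
Shanxi,Central,managerial,0.0160,0.0036,0.0075,8
Anhui,Central,managerial,0.0048,0.0021,0.0031,24
Heilongjiang,Central,managerial,0.0175,0.0012,0.0046,17
Shaanxi,Western,managerial,0.0191,0.0037,0.0084,6
Yunnan,Western,managerial,0.0064,0.0008,0.0023,27
Guangxi,Western,managerial,0.0072,0.0015,0.0033,22
Guizhou,Western,managerial,0.0148,0.0032,0.0069,9
Sichuan,Western,managerial,0.0115,0.0020,0.0048,16
Ningxia,Western,managerial,0.0058,0.0006,0.0019,29
Chongqing,Western,managerial,0.0090,0.0035,0.0056,12
Gansu,Western,managerial,0.0182,0.0010,0.0043,18
Inner Mongolia,Western,managerial,0.0169,0.0003,0.0024,26
Xinjiang,Western,managerial,0.0171,0.0003,0.0021,28
Qinghai,Western,managerial,0.0108,0.0001,0.0010,30
Tibet,Western,managerial,0.0178,0.0001,0.0010,31
Shanghai,Eastern,workforce_technical,0.0054,0.0214,0.0108,2
Beijing,Eastern,workforce_technical,0.0057,0.0074,0.0065,14
Tianjin,Eastern,workforce_technical,0.0074,0.0091,0.0082,6
Jiangsu,Eastern,workforce_technical,0.0080,0.0066,0.0072,9
Shandong,Eastern,workforce_technical,0.0065,0.0043,0.0052,18
Hainan,Eastern,workforce_technical,0.0182,0.0054,0.0099,4
Zhejiang,Eastern,workforce_technical,0.0053,0.0034,0.0043,23
Fujian,Eastern,workforce_technical,0.0136,0.0046,0.0079,8
Guangdong,Eastern,workforce_technical,0.0095,0.0066,0.0079,7
Liaoning,Eastern,workforce_technical,0.0103,0.0030,0.0055,17
Hebei,Eastern,workforce_technical,0.0151,0.0060,0.0095,5
Henan,Central,workforce_technical,0.0366,0.0218,0.0282,1
Hubei,Central,workforce_technical,0.0094,0.0029,0.0052,19
Hunan,Central,workforce_technical,0.0177,0.0055,0.0099,3
Jiangxi,Central,workforce_technical,0.0109,0.0029,0.0057,16
Jilin,Central,workforce_technical,0.0120,0.0015,0.0043,22
Shanxi,Central,workforce_technical,0.0150,0.0033,0.0071,10
Anhui,Central,workforce_technical,0.0055,0.0024,0.0036,25
Heilongjiang,Central,workforce_technical,0.0127,0.0009,0.0034,27
Shaanxi,Western,workforce_technical,0.0153,0.0029,0.0067,12
Yunnan,Western,workforce_technical,0.0173,0.0021,0.0061,15
Guangxi,Western,workforce_technical,0.0149,0.0032,0.0069,11
Guizhou,Western,workforce_technical,0.0073,0.0016,0.0034,26
Sichuan,Western,workforce_technical,0.0158,0.0027,0.0066,13
Ningxia,Western,workforce_technical,0.0111,0.0012,0.0037,24
Chongqing,Western,workforce_technical,0.0076,0.0030,0.0048,20
Gansu,Western,workforce_technical,0.0186,0.0010,0.0044,21
Inner Mongolia,Western,workforce_technical,0.0155,0.0003,0.0022,28
Xinjiang,Western,workforce_technical,0.0162,0.0003,0.0020,29
Qinghai,Western,workforce_technical,0.0199,0.0002,0.0018,30
Tibet,Western,workforce_technical,0.0238,0.0001,0.0013,31
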