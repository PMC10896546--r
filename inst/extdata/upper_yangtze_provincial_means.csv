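year,Sichuan,Chongqing,Guizhou,Yunnan
2010,0.530,0.424,0.311,0.319
2011,0.552,0.430,0.236,0.300
2012,0.519,0.444,0.275,0.313
2013,0.526,0.452,0.281,0.327
2014,0.517,0.451,0.337,0.333
2015,0.565,0.455,0.373,0.366
2016,0.611,0.486,0.400,0.371
2017,0.614,0.493,0.433,0.378
2018,0.650,0.518,0.465,0.373
2019,0.728,0.542,0.508,0.416
2020,0.844,0.589,0.603,0.454
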