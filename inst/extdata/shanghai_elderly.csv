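year,Huangpu,Xuhui,Changning,Jing'an,Putuo,Hongkou,Yangpu,Minhang,Baoshan,Jiading,Pudongxin,Jinshan,Songjiang,Qingpu,Fengxian,Chongming
2006,19.78,19.19,12.54,21.43,17.58,16.86,21.25,16.57,15.74,11.24,49.57,9.65,9.97,8.83,9.67,15.76
2007,20.3,19.89,12.88,22,18.3,17.47,21.97,17.57,16.6,11.75,52.1,10.03,10.42,9.13,10.1,16.33
2008,21.07,20.77,13.39,22.82,19.31,18.31,23.12,18.86,17.81,13.36,55.13,10.5,10.93,9.49,10.59,16.85
2009,21.84,21.65,13.89,23.63,20.32,19.15,24.27,20.14,19.01,12.96,58.15,10.97,11.43,9.84,11.08,17.37
2010,22.6,22.47,14.46,24.7,21.47,19.95,25.46,21.48,20.22,13.62,61.28,11.43,12,10.27,11.61,17.99
2011,23.65,23.4,15.08,25.78,22.68,20.97,26.77,22.78,21.44,14.32,64.73,11.94,12.57,10.66,12.25,18.74
2012,24.82,24.4,15.78,27.16,24.12,22.1,28.32,24.22,22.91,15.19,68.63,12.6,13.35,11.23,12.96,19.53
2013,26.05,25.47,16.52,28.4,25.66,23.31,29.92,25.78,24.51,16.1,72.72,13.25,14.11,11.84,13.69,20.28
2014,27.69,26.95,17.57,30.23,27.68,24.82,32.08,27.77,26.56,17.26,77.9,14.07,15.1,12.6,14.56,21.14
2015,28.89,28.18,18.48,31.57,29.38,25.94,33.75,29.55,28.36,18.24,82.31,14.84,16,13.31,15.26,21.89
2016,30.16,29.42,19.42,32.65,31.12,27,35.48,31.3,30.33,19.3,86.57,15.59,16.83,13.98,15.89,22.77
2017,31.38,30.72,20.4,33.87,32.86,28.03,37.36,33.09,32.45,20.39,91.03,16.26,17.72,14.69,16.62,23.73
2018,32.6,32.01,21.37,35.09,34.59,29.06,39.23,34.87,34.56,21.48,95.49,16.92,18.6,15.39,17.34,24.68
2019,32.77,32.78,21.88,35.71,35.65,29.24,40.21,36.35,36.29,22.53,98.92,17.33,19.31,15.98,17.69,25.48
2020,32.56,33.48,22.42,36.29,36.68,29.48,41,37.83,38.02,23.58,102.35,17.74,20.02,16.57,18.04,26.28
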