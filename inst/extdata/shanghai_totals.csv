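year,Huangpu,Xuhui,Changning,Jing'an,Putuo,Hongkou,Yangpu,Minhang,Baoshan,Jiading,Pudongxin,Jinshan,Songjiang,Qingpu,Fengxian,Chongming
2006,91.56,88.75,61.42,100.82,85.97,78.7,107.75,85.83,81.59,53.25,260.29,52.29,53.21,45.63,51.33,69.98
2007,91.82,89.22,61.23,100.63,86.33,78.83,107.18,88.56,83.1,53.79,264.61,52.2,54.2,45.7,51.64,69.82
2008,91.41,89.93,61.31,100.31,86.8,79.06,107.91,91.42,84.77,54.41,268.45,51.97,55.07,45.82,51.76,69.42
2009,90.99,90.64,61.39,99.98,87.27,79.28,108.63,94.28,86.43,55.02,272.28,51.73,55.94,45.94,51.88,69.02
2010,90.63,91.09,61.61,99.72,87.89,79.06,109.16,96.75,88.29,55.75,275.8,51.66,57.6,46.19,52.18,68.95
2011,90.56,91.46,62.05,99.12,88.11,79.05,109.23,98.48,89.51,56.21,278.53,51.68,57.92,46.33,52.35,68.77
2012,90.36,91.69,62.65,98.79,88.38,79,109.32,100.12,90.65,56.71,281.12,51.7,58.88,46.5,52.53,68.54
2013,89.77,91.7,62.5,98.04,88.58,78.74,108.95,101.97,91.97,57.61,283.79,51.7,59.54,46.74,52.53,68.21
2014,88.71,91.82,59.24,97.35,89.26,78.3,108.86,104.52,93.6,58.83,288.44,51.79,60.57,46.94,52.69,67.78
2015,87.39,91.97,58.59,96.53,89.47,77.25,108.48,106.58,94.8,59.81,291.87,51.83,61.15,47.17,52.85,67.23
2016,86.12,92.08,58.33,95,89.61,75.97,107.85,109.08,96.46,61.21,295.77,52.04,62.43,47.78,53.19,67.07
2017,84.59,92.12,58.12,93.71,89.53,74.46,107.63,111.4,97.9,62.64,299.66,52.2,63.51,48.35,53.53,67.47
2018,83.05,92.16,57.91,92.41,89.44,72.95,107.41,113.71,99.33,64.07,303.54,52.36,64.59,48.92,53.87,67.86
2019,80.89,92.67,57.59,91.41,89.4,71.09,106.7,116.45,100.98,65.78,308.1,52.5,65.95,49.62,54.19,67.85
2020,78.11,93.2,57.41,90.53,89.29,69.43,105.65,119.19,102.63,67.49,312.66,52.64,67.31,50.32,54.51,67.84
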