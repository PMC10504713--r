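year,total_population,age60plus,age60_69,age70_79,age80plus
2006,1368.06,275.62,120.45,108.32,46.86
2007,1378.86,286.83,128.21,108.42,50.2
2008,1389.82,300.57,140.07,107.3,53.5
2009,1400.7,315.7,153.11,105.76,56.51
2010,1412.32,331.02,166.83,104.6,59.91
2011,1419.36,347.76,180.49,104.33,62.94
2012,1426.93,367.32,198.35,102.11,66.85
2013,1432.34,387.62,215.52,100.39,71.71
2014,1438.69,413.98,236.8,101.84,75.34
2015,1442.97,435.95,255.03,102.88,78.04
2016,1449.98,457.79,269.18,108.95,79.66
2017,1456.82,483.6,283.87,118.48,81.24
2018,1463.61,503.28,295.43,126.83,81.53
2019,1471.16,518.12,297.4,138.86,81.86
2020,1478.09,533.49,299.82,150.98,82.69
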