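indicator,label,n,mean,sd
sleep_time,Mon,463,1346,81.3
sleep_time,Tue,459,1355,94.53
sleep_time,Wed,458,1351,86.22
sleep_time,Thu,460,1353,99.67
sleep_time,Fri,463,1374,89.2
sleep_time,Sat,464,1383,104.04
sleep_time,Sun,466,1356,85.27
wake_time,Mon,463,366,70.6
wake_time,Tue,459,354,74.22
wake_time,Wed,458,363,73.7
wake_time,Thu,460,364,84.86
wake_time,Fri,463,365,72.76
wake_time,Sat,464,420,101.23
wake_time,Sun,466,428,79.51
duration,Mon,463,449.1,95.83
duration,Tue,459,447.76,97.47
duration,Wed,458,449.88,92.13
duration,Thu,460,449.73,96.21
duration,Fri,463,477.99,110.99
duration,Sat,464,483.25,111.16
duration,Sun,466,450.18,89.15
home_time,Mon,463,516.47,216.85
home_time,Tue,459,486.14,215.28
home_time,Wed,458,503.46,219.69
home_time,Thu,460,482.41,213.16
home_time,Fri,463,498.95,223.06
home_time,Sat,462,533.51,215.45
home_time,Sun,466,576.27,220.66
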