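indicator,label,n,mean,sd
sleep_time,spring,461,1352,98.5
sleep_time,summer,455,1352,108.37
sleep_time,fall,461,1345,89.12
sleep_time,winter,466,1355,107.11
wake_time,spring,461,382,93.05
wake_time,summer,455,391,84.75
wake_time,fall,461,386,88.36
wake_time,winter,466,386,102.75
duration,spring,461,466.54,106.23
duration,summer,455,472.54,109.59
duration,fall,461,477.83,106.2
duration,winter,466,465.05,110.65
home_time,spring,461,523.13,227.56
home_time,summer,455,486.58,237.4
home_time,fall,461,529.39,226.42
home_time,winter,466,546.43,235.53
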