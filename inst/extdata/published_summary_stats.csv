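series,mean_ms,sd_ms
duration,976.1,205.7
IOI,8578.3,7807.4
IPI,8574.6,7839.8
IOI_short,1983.2,722.1
IPI_short,2020.8,803.3
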