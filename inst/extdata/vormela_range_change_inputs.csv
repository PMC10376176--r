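period,scenario,current,loss,stable,gain
2050,SSP126,3067.93,978.64,2089.29,137.14
2050,SSP245,3067.93,646.18,2421.75,132.04
2050,SSP585,3067.93,926.29,2141.64,85.02
2090,SSP126,3067.93,546.16,2521.77,180.66
2090,SSP245,3067.93,1099.21,1968.72,70.06
2090,SSP585,3067.93,978.59,2089.34,124.14
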