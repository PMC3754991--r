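id,age,d15n
synth001,2.81122623989359,9.99355284569069
synth002,0.858418604359031,12.8840118401063
synth003,2.49134287820198,10.8466057934093
synth004,1.92523655667901,11.9084729065025
synth005,1.5572878473904,12.2697558933613
synth006,2.2097649439238,11.4873428026617
synth007,0.403999791713431,11.7903718636733
synth008,1.97097687120549,11.7677590533253
synth009,2.11519435211085,11.0900491351586
synth010,1.37322532874532,12.2841083373554
synth011,2.15733675495721,11.2374749013945
synth012,2.80401674145833,10.9124265437326
synth013,0.766286473022774,12.9169692395647
synth014,6.23604975780472,9.61502966938536
synth015,9.58010165928863,9.59139179501544
synth016,9.84758499870077,9.38231342546818
synth017,3.82241153158247,9.89016687502814
synth018,6.3249795709271,9.70827558754662
synth019,6.92232922371477,9.21941177275738
synth020,9.32821971108206,9.51161250928926
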