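fragment,formula,carbons
Ala,C3H7NO2,3
Gly,C2H5NO2,2
Ser,C3H7NO3,3
Val,C5H11NO2,5
Thr,C4H9NO3,4
Asp,C4H7NO4,4
Glu,C5H9NO4,5
Arg,C6H14N4O2,6
Lys,C6H14N2O2,6
Ile,C6H13NO2,6
Phe,C9H11NO2,9
Tyr,C9H11NO3,9
His,C6H9N3O2,6
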