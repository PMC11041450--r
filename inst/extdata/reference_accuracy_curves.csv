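criterion,approach,k,accuracy
cost,typology,1,80.00
cost,typology,2,75.00
cost,typology,3,60.78
cost,typology,4,66.67
cost,typology,5,60.00
cost,typology,6,54.55
cost,hybrid,1,100.00
cost,hybrid,2,92.50
cost,hybrid,3,86.67
cost,hybrid,4,76.25
cost,hybrid,5,67.00
cost,hybrid,6,59.65
harm,typology,1,100.00
harm,typology,2,97.50
harm,typology,3,86.67
harm,typology,4,76.39
harm,typology,5,72.94
harm,typology,6,66.67
harm,hybrid,1,90.00
harm,hybrid,2,90.00
harm,hybrid,3,90.00
harm,hybrid,4,85.00
harm,hybrid,5,81.00
harm,hybrid,6,75.83
conflict,typology,1,75.00
conflict,typology,2,72.50
conflict,typology,3,66.67
conflict,typology,4,61.11
conflict,typology,5,55.29
conflict,typology,6,56.41
conflict,hybrid,1,90.00
conflict,hybrid,2,87.50
conflict,hybrid,3,81.67
conflict,hybrid,4,68.75
conflict,hybrid,5,59.00
conflict,hybrid,6,50.93
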