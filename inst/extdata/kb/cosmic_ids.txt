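# Catalog identifiers of somatic mutations (bundled testing subset)
COSM476
COSM516
COSM517
COSM518
COSM521
COSM532
COSM554
COSM563
COSM564
COSM565
COSM566
COSM580
COSM581
COSM584
COSM586
COSM763
COSM775
COSM783
COSM1290
COSM1311
COSM1314
COSM10648
COSM10656
COSM10660
COSM10758
COSM12600
COSM28747
COSM33733
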