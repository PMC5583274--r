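analyte_id,q1_mz,q3_mz,polarity,rt_min,declustering_potential,collision_energy,chem_class,pathway,is_internal_standard
met_0001,485.68175413412973,433.93023767508566,negative,14.658340992215706,105,10.4,bile acid,pathway_01,FALSE
met_0002,847.483961796388,789.5490874489769,positive,18.502889399837457,38.9,28.8,nucleoside,pathway_02,FALSE
met_0003,755.9639245271683,741.8465109122917,negative,19.62634532002764,47.1,35.7,phospholipid,pathway_03,FALSE
met_0004,824.2812813795172,707.191890864633,positive,18.673730364814254,102.8,10.1,vitamin,pathway_04,FALSE
met_0005,430.94070301856846,373.4480656404048,positive,16.56138174037812,89.3,39.1,fatty acid,pathway_05,FALSE
met_0006,707.2078483458608,591.8744227150455,negative,23.310350267178382,44.1,17.9,phospholipid,pathway_06,FALSE
met_0007,73.67195507977158,30,negative,16.608779771429553,24.3,28,vitamin,pathway_07,FALSE
met_0008,844.6119546354748,764.214289993979,positive,25.318535482261197,34,42.3,sphingolipid,pathway_08,FALSE
met_0009,76.82075659977272,30,positive,16.740821712211535,41.6,48.8,organic acid,pathway_09,FALSE
met_0010,263.1228447263129,185.0506419199519,positive,22.450284968412255,67.9,38.2,organic acid,pathway_10,FALSE
istd_001,913.1393092521466,866.4623160124756,positive,11.198628528041864,39.7,21.7,internal standard,NA,TRUE
istd_002,638.9541384065524,590.8118311036378,positive,15.846865891420975,91.9,14.5,internal standard,NA,TRUE
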