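"Q","100% ACN + 0% DXN","80% ACN + 20% DXN","60% ACN + 40% DXN","40% ACN + 60% DXN","20% ACN + 80% DXN","0% ACN + 100% DXN"
"0.00","4665.500","3747.270","3600.000","3560.000","3500.000","3028.000"
"0.02","3301.952","2867.341","2873.643","2768.762","2892.044","2564.158"
"0.04","2421.604","2184.928","2329.616","2160.823","2389.436","2144.113"
"0.06","1818.371","1669.565","1891.168","1674.593","1959.627","1760.470"
"0.08","1394.835","1229.971","1558.597","1278.738","1587.816","1410.314"
"0.10","1069.995","963.880","1232.003","929.138","1253.798","1084.714"
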