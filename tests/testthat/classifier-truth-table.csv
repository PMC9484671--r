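esa,pka,ss3,h_donor,low_positive_charge,expected
0,10,helix,FALSE,FALSE,non_reacting
49.99,10,helix,FALSE,FALSE,non_reacting
50,10,helix,FALSE,FALSE,slow_reacting
200,10,helix,FALSE,FALSE,slow_reacting
0,10.3,helix,FALSE,FALSE,non_reacting
49.99,10.3,helix,FALSE,FALSE,non_reacting
50,10.3,helix,FALSE,FALSE,slow_reacting
200,10.3,helix,FALSE,FALSE,slow_reacting
0,10.31,helix,FALSE,FALSE,non_reacting
49.99,10.31,helix,FALSE,FALSE,non_reacting
50,10.31,helix,FALSE,FALSE,slow_reacting
200,10.31,helix,FALSE,FALSE,slow_reacting
0,10,strand,FALSE,FALSE,non_reacting
49.99,10,strand,FALSE,FALSE,non_reacting
50,10,strand,FALSE,FALSE,slow_reacting
200,10,strand,FALSE,FALSE,slow_reacting
0,10.3,strand,FALSE,FALSE,non_reacting
49.99,10.3,strand,FALSE,FALSE,non_reacting
50,10.3,strand,FALSE,FALSE,slow_reacting
200,10.3,strand,FALSE,FALSE,slow_reacting
0,10.31,strand,FALSE,FALSE,non_reacting
49.99,10.31,strand,FALSE,FALSE,non_reacting
50,10.31,strand,FALSE,FALSE,slow_reacting
200,10.31,strand,FALSE,FALSE,slow_reacting
0,10,coil,FALSE,FALSE,non_reacting
49.99,10,coil,FALSE,FALSE,non_reacting
50,10,coil,FALSE,FALSE,slow_reacting
200,10,coil,FALSE,FALSE,slow_reacting
0,10.3,coil,FALSE,FALSE,non_reacting
49.99,10.3,coil,FALSE,FALSE,non_reacting
50,10.3,coil,FALSE,FALSE,slow_reacting
200,10.3,coil,FALSE,FALSE,slow_reacting
0,10.31,coil,FALSE,FALSE,non_reacting
49.99,10.31,coil,FALSE,FALSE,non_reacting
50,10.31,coil,FALSE,FALSE,slow_reacting
200,10.31,coil,FALSE,FALSE,slow_reacting
0,10,helix,TRUE,FALSE,non_reacting
49.99,10,helix,TRUE,FALSE,non_reacting
50,10,helix,TRUE,FALSE,slow_reacting
200,10,helix,TRUE,FALSE,slow_reacting
0,10.3,helix,TRUE,FALSE,non_reacting
49.99,10.3,helix,TRUE,FALSE,non_reacting
50,10.3,helix,TRUE,FALSE,slow_reacting
200,10.3,helix,TRUE,FALSE,slow_reacting
0,10.31,helix,TRUE,FALSE,non_reacting
49.99,10.31,helix,TRUE,FALSE,non_reacting
50,10.31,helix,TRUE,FALSE,slow_reacting
200,10.31,helix,TRUE,FALSE,slow_reacting
0,10,strand,TRUE,FALSE,non_reacting
49.99,10,strand,TRUE,FALSE,non_reacting
50,10,strand,TRUE,FALSE,slow_reacting
200,10,strand,TRUE,FALSE,slow_reacting
0,10.3,strand,TRUE,FALSE,non_reacting
49.99,10.3,strand,TRUE,FALSE,non_reacting
50,10.3,strand,TRUE,FALSE,slow_reacting
200,10.3,strand,TRUE,FALSE,slow_reacting
0,10.31,strand,TRUE,FALSE,non_reacting
49.99,10.31,strand,TRUE,FALSE,non_reacting
50,10.31,strand,TRUE,FALSE,slow_reacting
200,10.31,strand,TRUE,FALSE,slow_reacting
0,10,coil,TRUE,FALSE,non_reacting
49.99,10,coil,TRUE,FALSE,non_reacting
50,10,coil,TRUE,FALSE,slow_reacting
200,10,coil,TRUE,FALSE,slow_reacting
0,10.3,coil,TRUE,FALSE,non_reacting
49.99,10.3,coil,TRUE,FALSE,non_reacting
50,10.3,coil,TRUE,FALSE,slow_reacting
200,10.3,coil,TRUE,FALSE,slow_reacting
0,10.31,coil,TRUE,FALSE,non_reacting
49.99,10.31,coil,TRUE,FALSE,non_reacting
50,10.31,coil,TRUE,FALSE,slow_reacting
200,10.31,coil,TRUE,FALSE,slow_reacting
0,10,helix,FALSE,TRUE,non_reacting
49.99,10,helix,FALSE,TRUE,non_reacting
50,10,helix,FALSE,TRUE,slow_reacting
200,10,helix,FALSE,TRUE,slow_reacting
0,10.3,helix,FALSE,TRUE,non_reacting
49.99,10.3,helix,FALSE,TRUE,non_reacting
50,10.3,helix,FALSE,TRUE,slow_reacting
200,10.3,helix,FALSE,TRUE,slow_reacting
0,10.31,helix,FALSE,TRUE,non_reacting
49.99,10.31,helix,FALSE,TRUE,non_reacting
50,10.31,helix,FALSE,TRUE,slow_reacting
200,10.31,helix,FALSE,TRUE,slow_reacting
0,10,strand,FALSE,TRUE,non_reacting
49.99,10,strand,FALSE,TRUE,non_reacting
50,10,strand,FALSE,TRUE,fast_reacting
200,10,strand,FALSE,TRUE,fast_reacting
0,10.3,strand,FALSE,TRUE,non_reacting
49.99,10.3,strand,FALSE,TRUE,non_reacting
50,10.3,strand,FALSE,TRUE,fast_reacting
200,10.3,strand,FALSE,TRUE,fast_reacting
0,10.31,strand,FALSE,TRUE,non_reacting
49.99,10.31,strand,FALSE,TRUE,non_reacting
50,10.31,strand,FALSE,TRUE,slow_reacting
200,10.31,strand,FALSE,TRUE,slow_reacting
0,10,coil,FALSE,TRUE,non_reacting
49.99,10,coil,FALSE,TRUE,non_reacting
50,10,coil,FALSE,TRUE,fast_reacting
200,10,coil,FALSE,TRUE,fast_reacting
0,10.3,coil,FALSE,TRUE,non_reacting
49.99,10.3,coil,FALSE,TRUE,non_reacting
50,10.3,coil,FALSE,TRUE,fast_reacting
200,10.3,coil,FALSE,TRUE,fast_reacting
0,10.31,coil,FALSE,TRUE,non_reacting
49.99,10.31,coil,FALSE,TRUE,non_reacting
50,10.31,coil,FALSE,TRUE,slow_reacting
200,10.31,coil,FALSE,TRUE,slow_reacting
0,10,helix,TRUE,TRUE,non_reacting
49.99,10,helix,TRUE,TRUE,non_reacting
50,10,helix,TRUE,TRUE,slow_reacting
200,10,helix,TRUE,TRUE,slow_reacting
0,10.3,helix,TRUE,TRUE,non_reacting
49.99,10.3,helix,TRUE,TRUE,non_reacting
50,10.3,helix,TRUE,TRUE,slow_reacting
200,10.3,helix,TRUE,TRUE,slow_reacting
0,10.31,helix,TRUE,TRUE,non_reacting
49.99,10.31,helix,TRUE,TRUE,non_reacting
50,10.31,helix,TRUE,TRUE,slow_reacting
200,10.31,helix,TRUE,TRUE,slow_reacting
0,10,strand,TRUE,TRUE,non_reacting
49.99,10,strand,TRUE,TRUE,non_reacting
50,10,strand,TRUE,TRUE,slow_reacting
200,10,strand,TRUE,TRUE,slow_reacting
0,10.3,strand,TRUE,TRUE,non_reacting
49.99,10.3,strand,TRUE,TRUE,non_reacting
50,10.3,strand,TRUE,TRUE,slow_reacting
200,10.3,strand,TRUE,TRUE,slow_reacting
0,10.31,strand,TRUE,TRUE,non_reacting
49.99,10.31,strand,TRUE,TRUE,non_reacting
50,10.31,strand,TRUE,TRUE,slow_reacting
200,10.31,strand,TRUE,TRUE,slow_reacting
0,10,coil,TRUE,TRUE,non_reacting
49.99,10,coil,TRUE,TRUE,non_reacting
50,10,coil,TRUE,TRUE,slow_reacting
200,10,coil,TRUE,TRUE,slow_reacting
0,10.3,coil,TRUE,TRUE,non_reacting
49.99,10.3,coil,TRUE,TRUE,non_reacting
50,10.3,coil,TRUE,TRUE,slow_reacting
200,10.3,coil,TRUE,TRUE,slow_reacting
0,10.31,coil,TRUE,TRUE,non_reacting
49.99,10.31,coil,TRUE,TRUE,non_reacting
50,10.31,coil,TRUE,TRUE,slow_reacting
200,10.31,coil,TRUE,TRUE,slow_reacting
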