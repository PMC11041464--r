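participant,initial_threshold,stimulus,coh,reported_mean
1,0.660,1,0.698,0.609
1,0.660,2,0.557,0.609
1,0.660,3,0.363,0.609
1,0.660,4,0.718,0.609
1,0.660,5,0.700,0.609
1,0.660,6,0.661,0.609
1,0.660,7,0.664,0.609
1,0.660,8,0.684,0.609
1,0.660,9,0.435,0.609
1,0.660,10,0.607,0.609
2,0.770,1,0.856,0.773
2,0.770,2,0.777,0.773
2,0.770,3,0.792,0.773
2,0.770,4,0.786,0.773
2,0.770,5,0.828,0.773
2,0.770,6,0.781,0.773
2,0.770,7,0.826,0.773
2,0.770,8,0.744,0.773
2,0.770,9,0.817,0.773
2,0.770,10,0.579,0.773
3,0.530,1,0.624,0.560
3,0.530,2,0.632,0.560
3,0.530,3,0.569,0.560
3,0.530,4,0.627,0.560
3,0.530,5,0.551,0.560
3,0.530,6,0.571,0.560
3,0.530,7,0.545,0.560
3,0.530,8,0.620,0.560
3,0.530,9,0.559,0.560
3,0.530,10,0.430,0.560
4,0.570,1,0.635,0.601
4,0.570,2,0.388,0.601
4,0.570,3,0.580,0.601
4,0.570,4,0.950,0.601
4,0.570,5,0.600,0.601
4,0.570,6,0.416,0.601
4,0.570,7,0.445,0.601
4,0.570,8,0.669,0.601
4,0.570,9,0.648,0.601
4,0.570,10,0.684,0.601
5,0.695,1,0.720,0.750
5,0.695,2,0.937,0.750
5,0.695,3,0.612,0.750
5,0.695,4,0.754,0.750
5,0.695,5,0.962,0.750
5,0.695,6,0.657,0.750
5,0.695,7,0.719,0.750
5,0.695,8,0.746,0.750
5,0.695,9,0.955,0.750
5,0.695,10,0.442,0.750
6,0.671,1,0.672,0.692
6,0.671,2,0.676,0.692
6,0.671,3,0.748,0.692
6,0.671,4,0.724,0.692
6,0.671,5,0.762,0.692
6,0.671,6,0.696,0.692
6,0.671,7,0.702,0.692
6,0.671,8,0.671,0.692
6,0.671,9,0.685,0.692
6,0.671,10,0.672,0.692
7,0.670,1,0.672,0.464
7,0.670,2,0.341,0.464
7,0.670,3,0.557,0.464
7,0.670,4,0.271,0.464
7,0.670,5,0.606,0.464
7,0.670,6,0.403,0.464
7,0.670,7,0.359,0.464
7,0.670,8,0.633,0.464
7,0.670,9,0.475,0.464
7,0.670,10,0.322,0.464
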