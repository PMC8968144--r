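index,hc,case1,case2
average_degree,77.915,30.582,36.606
average_strength_w,3.048,1.233,1.396
clustering_coef,0.76,0.614,0.604
clustering_coef_w,0.019,0.017,0.015
char_path_length,1.542,2.092,1.927
char_path_length_w,18.302,35.211,28.544
global_efficiency,0.735,0.549,0.587
global_efficiency_w,0.068,0.039,0.045
small_worldness,1.591,2.881,2.531
modularity,0.193,0.38,0.351
coreness,0.321,0.402,0.367
density,47.51,18.65,22.32
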