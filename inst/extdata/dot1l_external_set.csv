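label,pic50,glide_score,vina_score,dnn_score
C170206_10,5.19,-7.627,-8.5,0.8542
C170206_15,5.40,-7.915,-8.4,0.9927
C170206_16,5.08,-7.898,-9.9,0.9821
C170206_17,5.35,-5.374,-8.8,0.555
C170206_39,5.39,-8.233,-8.8,0.9007
C170206_6,5.08,-6.629,-8.7,0.8713
C170206_9,5.33,-7.839,-8.4,0.9439
C170214_3,5.05,-8.322,-8.3,0.6092
C170214_4,8.4,-9.432,-8.3,0.0141
C170214_5,8.4,-7.773,-9.6,0.8417
C170214_6,9.82,-10.445,-9.2,0.9239
C170214_7,8.52,-9.125,-8.8,0.9996
C180224_6,5.15,-5.67,-7.9,0.8878
C180224_7,5.03,-7.471,-8.3,0.6535
C180224_9,5.01,-6.375,-7.8,0.9412
C180722_3a,5.82,-6.461,-9.8,0.7206
C180722_3b,5.36,-7.745,-9.1,0.8655
C180722_3d,5.97,-8.945,-10.1,0.7807
C180722_3e,5.97,-6.465,-9.3,0.7952
C180722_8b,5.11,-5.558,-8.3,0.9847
C180722_8f,5.22,-7.641,-9.9,0.5408
C180722_8h,5.24,-5.082,-8.6,0.2014
C180722_8i,5.1,-5.542,-9,0.9797
C180722_9b,5.06,-7.433,-8.7,0.9993
C180722_9e,5.45,-7.664,-9.3,0.9985
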