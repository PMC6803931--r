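# synthetic rate table generated from the bundled OH+H2 AM parameters
# (lognormal noise, sigma = 0.03, seed = 7)
T_K,k_cm3.molecule.s
200,3.57925e-16
242.105,1.34576e-15
284.211,4.19724e-15
326.316,1.0504e-14
368.421,2.19362e-14
410.526,4.14442e-14
452.632,7.51451e-14
494.737,1.17357e-13
536.842,1.78841e-13
578.947,2.7389e-13
621.053,3.58829e-13
663.158,5.15478e-13
705.263,6.61747e-13
747.368,7.91929e-13
789.474,1.03147e-12
831.579,1.20535e-12
873.684,1.38872e-12
915.789,1.67225e-12
957.895,1.97153e-12
1000,2.34646e-12
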