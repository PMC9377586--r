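sex,region,thickness_mm,iterations,c1_mpa,k_mpa,e_mpa
female,upper_arm,18.93,4,0.00358,3.58,0.02148
female,lower_arm,9.19,8,0.00133,1.33,0.00798
female,upper_leg,21.17,2,0.00779,7.79,0.04674
female,lower_leg,26.09,4,0.00808,8.08,0.04848
male,upper_arm,38.32,4,0.00342,3.42,0.02052
male,lower_arm,40.60,3,0.00596,5.96,0.03576
male,upper_leg,31.49,3,0.01143,11.43,0.06858
male,lower_leg,32.43,3,0.00830,8.30,0.04980
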