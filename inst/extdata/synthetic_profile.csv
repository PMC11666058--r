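# synthetic bacterial accumulation profile (generated by plumequench::synth_profile)
# generating RDF: beta0=1.00 beta_m=23.9 d_s=0.42 n=1; lognormal noise sigma=0.08, seed=101
r,b
1,24.2589
1.08475,21.4608
1.16949,16.0722
1.25424,14.2899
1.33898,11.9566
1.42373,10.6712
1.50847,8.53445
1.59322,6.75963
1.67797,6.19551
1.76271,4.80148
1.84746,4.35729
1.9322,3.37537
2.01695,3.50026
2.10169,2.43185
2.18644,2.37233
2.27119,2.12551
2.35593,1.81897
2.44068,1.78222
2.52542,1.52913
2.61017,1.28745
2.69492,1.40396
2.77966,1.42373
2.86441,1.25499
2.94915,1.09462
3.0339,1.26142
3.11864,1.03091
3.20339,1.16876
3.28814,1.09242
3.37288,1.12538
3.45763,1.11218
3.54237,1.13456
3.62712,1.06953
3.71186,1.12464
3.79661,0.873151
3.88136,1.12743
3.9661,0.963025
4.05085,1.03049
4.13559,1.09113
4.22034,0.884609
4.30508,1.046
4.38983,1.04711
4.47458,1.06902
4.55932,0.834794
4.64407,0.967837
4.72881,0.918416
4.81356,1.03557
4.89831,1.0489
4.98305,0.946798
5.0678,0.978512
5.15254,0.889144
5.23729,0.912992
5.32203,0.979075
5.40678,1.04801
5.49153,0.894751
5.57627,1.06223
5.66102,0.919677
5.74576,1.01362
5.83051,1.09486
5.91525,1.09866
6,0.966506
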