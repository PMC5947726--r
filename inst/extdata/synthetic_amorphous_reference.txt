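0.05 0.016432
0.06 0.017302
0.07 0.01821
0.08 0.019155
0.09 0.02014
0.1 0.021164
0.11 0.02223
0.12 0.023338
0.13 0.02449
0.14 0.025685
0.15 0.026925
0.16 0.028212
0.17 0.029545
0.18 0.030926
0.19 0.032355
0.2 0.033834
0.21 0.035363
0.22 0.036942
0.23 0.038574
0.24 0.040257
0.25 0.041993
0.26 0.043783
0.27 0.045626
0.28 0.047523
0.29 0.049475
0.3 0.051481
0.31 0.053542
0.32 0.055659
0.33 0.05783
0.34 0.060057
0.35 0.062338
0.36 0.064674
0.37 0.067065
0.38 0.069509
0.39 0.072007
0.4 0.074559
0.41 0.077162
0.42 0.079817
0.43 0.082522
0.44 0.085277
0.45 0.08808
0.46 0.090931
0.47 0.093828
0.48 0.096769
0.49 0.099753
0.5 0.102778
0.51 0.105843
0.52 0.108945
0.53 0.112083
0.54 0.115254
0.55 0.118457
0.56 0.121688
0.57 0.124946
0.58 0.128228
0.59 0.131531
0.6 0.134852
0.61 0.138189
0.62 0.141539
0.63 0.144898
0.64 0.148264
0.65 0.151633
0.66 0.155002
0.67 0.158368
0.68 0.161728
0.69 0.165077
0.7 0.168413
0.71 0.171733
0.72 0.175032
0.73 0.178307
0.74 0.181556
0.75 0.184775
0.76 0.187962
0.77 0.191115
0.78 0.194232
0.79 0.197311
0.8 0.200354
0.81 0.203361
0.82 0.206336
0.83 0.209284
0.84 0.212213
0.85 0.215133
0.86 0.218061
0.87 0.221017
0.88 0.224027
0.89 0.227126
0.9 0.230355
0.91 0.233766
0.92 0.237424
0.93 0.241404
0.94 0.245796
0.95 0.250705
0.96 0.256252
0.97 0.262577
0.98 0.269833
0.99 0.278192
1 0.28784
1.01 0.298976
1.02 0.311809
1.03 0.326553
1.04 0.343422
1.05 0.362623
1.06 0.38435
1.07 0.408771
1.08 0.436024
1.09 0.466203
1.1 0.499352
1.11 0.53545
1.12 0.574406
1.13 0.616049
1.14 0.660127
1.15 0.706295
1.16 0.754123
1.17 0.803094
1.18 0.852611
1.19 0.902005
1.2 0.950551
1.21 0.997481
1.22 1.042005
1.23 1.08333
1.24 1.120686
1.25 1.153345
1.26 1.180646
1.27 1.202015
1.28 1.216986
1.29 1.225214
1.3 1.226489
1.31 1.220741
1.32 1.208047
1.33 1.188622
1.34 1.162817
1.35 1.131105
1.36 1.094065
1.37 1.052365
1.38 1.006738
1.39 0.957962
1.4 0.906833
1.41 0.854147
1.42 0.800679
1.43 0.747158
1.44 0.694258
1.45 0.642581
1.46 0.59265
1.47 0.544899
1.48 0.499676
1.49 0.457239
1.5 0.417762
1.51 0.38134
1.52 0.347997
1.53 0.317693
1.54 0.290337
1.55 0.265794
1.56 0.243898
1.57 0.224457
1.58 0.207267
1.59 0.192115
1.6 0.178789
1.61 0.167081
1.62 0.156793
1.63 0.14774
1.64 0.139751
1.65 0.132671
1.66 0.126363
1.67 0.120705
1.68 0.11559
1.69 0.110929
1.7 0.106644
1.71 0.102671
1.72 0.098956
1.73 0.095456
1.74 0.092135
1.75 0.088964
1.76 0.085921
1.77 0.082989
1.78 0.080152
1.79 0.077401
1.8 0.074728
1.81 0.072127
1.82 0.069593
1.83 0.067123
1.84 0.064714
1.85 0.062365
1.86 0.060075
1.87 0.057843
1.88 0.055667
1.89 0.053548
1.9 0.051485
1.91 0.049477
1.92 0.047525
1.93 0.045627
1.94 0.043783
1.95 0.041994
1.96 0.040257
1.97 0.038574
1.98 0.036943
1.99 0.035363
2 0.033834
2.01 0.032355
2.02 0.030926
2.03 0.029545
2.04 0.028212
2.05 0.026925
2.06 0.025685
2.07 0.02449
2.08 0.023338
2.09 0.02223
2.1 0.021164
2.11 0.02014
2.12 0.019155
2.13 0.01821
2.14 0.017302
2.15 0.016432
2.16 0.015598
2.17 0.014799
2.18 0.014034
2.19 0.013302
2.2 0.012601
2.21 0.011932
2.22 0.011293
2.23 0.010683
2.24 0.0101
2.25 0.009545
2.26 0.009016
2.27 0.008512
2.28 0.008032
2.29 0.007575
2.3 0.007141
2.31 0.006729
2.32 0.006337
2.33 0.005965
2.34 0.005612
2.35 0.005277
2.36 0.00496
2.37 0.00466
2.38 0.004376
2.39 0.004107
2.4 0.003852
2.41 0.003612
2.42 0.003385
2.43 0.00317
2.44 0.002968
2.45 0.002777
2.46 0.002597
2.47 0.002428
2.48 0.002269
2.49 0.002119
2.5 0.001978
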