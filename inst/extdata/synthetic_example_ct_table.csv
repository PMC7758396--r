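patient_id,gene,replicate,ct
P0001,PMP22,1,37.153
P0001,PMP22,2,36.9
P0001,PMP22,3,36.851
P0001,GOLM1,1,36.944
P0001,GOLM1,2,37.128
P0001,GOLM1,3,37.048
P0001,LMTK2,1,30.537
P0001,LMTK2,2,30.846
P0001,LMTK2,3,30.657
P0001,EZH2,1,25.863
P0001,EZH2,2,26.04
P0001,EZH2,3,26.058
P0001,GSTP1,1,25.836
P0001,GSTP1,2,25.806
P0001,GSTP1,3,25.464
P0001,PCA3,1,34.43
P0001,PCA3,2,34.713
P0001,PCA3,3,34.782
P0001,VEGFA,1,35.958
P0001,VEGFA,2,36.063
P0001,VEGFA,3,36.238
P0001,CST3,1,40.581
P0001,CST3,2,40.498
P0001,CST3,3,40.622
P0001,PTEN,1,26.334
P0001,PTEN,2,26.448
P0001,PTEN,3,26.155
P0001,PIP5K1A,1,24.527
P0001,PIP5K1A,2,24.522
P0001,PIP5K1A,3,24.285
P0001,CDK1,1,25.282
P0001,CDK1,2,25.597
P0001,CDK1,3,25.644
P0001,TMPRSS2,1,35.596
P0001,TMPRSS2,2,35.62
P0001,TMPRSS2,3,35.391
P0001,ANXA3,1,29.416
P0001,ANXA3,2,29.407
P0001,ANXA3,3,29.476
P0001,CCND1,1,32.305
P0001,CCND1,2,32.314
P0001,CCND1,3,32.393
P0001,ACTB,1,25.084
P0001,ACTB,2,25.158
P0001,ACTB,3,25.006
P0002,PMP22,1,29.211
P0002,PMP22,2,29.307
P0002,PMP22,3,29.316
P0002,GOLM1,1,34.968
P0002,GOLM1,2,35.335
P0002,GOLM1,3,35.089
P0002,LMTK2,1,29.957
P0002,LMTK2,2,30.116
P0002,LMTK2,3,30.002
P0002,EZH2,1,27.017
P0002,EZH2,2,26.77
P0002,EZH2,3,26.736
P0002,GSTP1,1,26.504
P0002,GSTP1,2,26.399
P0002,GSTP1,3,26.431
P0002,PCA3,1,32.006
P0002,PCA3,2,31.997
P0002,PCA3,3,31.868
P0002,VEGFA,1,44.282
P0002,VEGFA,2,44.643
P0002,VEGFA,3,44.434
P0002,CST3,1,35.225
P0002,CST3,2,35.159
P0002,CST3,3,35.243
P0002,PTEN,1,36.363
P0002,PTEN,2,36.303
P0002,PTEN,3,36.651
P0002,PIP5K1A,1,28.04
P0002,PIP5K1A,2,27.913
P0002,PIP5K1A,3,27.812
P0002,CDK1,1,29.828
P0002,CDK1,2,29.614
P0002,CDK1,3,29.888
P0002,TMPRSS2,1,35.911
P0002,TMPRSS2,2,35.674
P0002,TMPRSS2,3,35.598
P0002,ANXA3,1,22.924
P0002,ANXA3,2,23.004
P0002,ANXA3,3,23.213
P0002,CCND1,1,31.371
P0002,CCND1,2,31.578
P0002,CCND1,3,31.505
P0002,ACTB,1,25.876
P0002,ACTB,2,25.651
P0002,ACTB,3,25.572
P0003,PMP22,1,32.734
P0003,PMP22,2,32.552
P0003,PMP22,3,32.598
P0003,GOLM1,1,23.526
P0003,GOLM1,2,23.79
P0003,GOLM1,3,23.664
P0003,LMTK2,1,32.573
P0003,LMTK2,2,32.791
P0003,LMTK2,3,32.446
P0003,EZH2,1,23.297
P0003,EZH2,2,23.053
P0003,EZH2,3,23.316
P0003,GSTP1,1,13.759
P0003,GSTP1,2,13.778
P0003,GSTP1,3,13.662
P0003,PCA3,1,27.675
P0003,PCA3,2,27.284
P0003,PCA3,3,27.276
P0003,VEGFA,1,35.924
P0003,VEGFA,2,35.782
P0003,VEGFA,3,36.032
P0003,CST3,1,45.525
P0003,CST3,2,45.82
P0003,CST3,3,44.964
P0003,PTEN,1,32.407
P0003,PTEN,2,32.615
P0003,PTEN,3,32.376
P0003,PIP5K1A,1,30.632
P0003,PIP5K1A,2,30.701
P0003,PIP5K1A,3,30.518
P0003,CDK1,1,25.174
P0003,CDK1,2,25.303
P0003,CDK1,3,25.318
P0003,TMPRSS2,1,37.186
P0003,TMPRSS2,2,37.431
P0003,TMPRSS2,3,37.354
P0003,ANXA3,1,27.671
P0003,ANXA3,2,27.491
P0003,ANXA3,3,27.498
P0003,CCND1,1,38.18
P0003,CCND1,2,37.957
P0003,CCND1,3,37.874
P0003,ACTB,1,23.479
P0003,ACTB,2,23.16
P0003,ACTB,3,23.152
P0004,PMP22,1,14.125
P0004,PMP22,2,14.252
P0004,PMP22,3,14.342
P0004,GOLM1,1,23.78
P0004,GOLM1,2,23.645
P0004,GOLM1,3,23.958
P0004,LMTK2,1,23.792
P0004,LMTK2,2,23.788
P0004,LMTK2,3,24.118
P0004,EZH2,1,25.084
P0004,EZH2,2,25.054
P0004,EZH2,3,25.105
P0004,GSTP1,1,24.364
P0004,GSTP1,2,24.281
P0004,GSTP1,3,24.812
P0004,PCA3,1,21.561
P0004,PCA3,2,21.469
P0004,PCA3,3,21.414
P0004,VEGFA,1,14.71
P0004,VEGFA,2,15.141
P0004,VEGFA,3,15.001
P0004,CST3,1,14.49
P0004,CST3,2,14.335
P0004,CST3,3,14.344
P0004,PTEN,1,19.255
P0004,PTEN,2,19.582
P0004,PTEN,3,19.084
P0004,PIP5K1A,1,30.647
P0004,PIP5K1A,2,30.94
P0004,PIP5K1A,3,30.584
P0004,CDK1,1,32.355
P0004,CDK1,2,31.934
P0004,CDK1,3,31.936
P0004,TMPRSS2,1,15.369
P0004,TMPRSS2,2,15.559
P0004,TMPRSS2,3,15.637
P0004,ANXA3,1,26.028
P0004,ANXA3,2,25.9
P0004,ANXA3,3,25.821
P0004,CCND1,1,25.258
P0004,CCND1,2,25.292
P0004,CCND1,3,25.202
P0004,ACTB,1,24.406
P0004,ACTB,2,24.191
P0004,ACTB,3,24.196
P0005,PMP22,1,22.764
P0005,PMP22,2,22.491
P0005,PMP22,3,22.77
P0005,GOLM1,1,21.069
P0005,GOLM1,2,21.118
P0005,GOLM1,3,21.111
P0005,LMTK2,1,22.992
P0005,LMTK2,2,23.2
P0005,LMTK2,3,23.172
P0005,EZH2,1,22.8
P0005,EZH2,2,22.74
P0005,EZH2,3,22.555
P0005,GSTP1,1,27.454
P0005,GSTP1,2,27.416
P0005,GSTP1,3,27.481
P0005,PCA3,1,27.638
P0005,PCA3,2,27.675
P0005,PCA3,3,27.602
P0005,VEGFA,1,17.257
P0005,VEGFA,2,17.649
P0005,VEGFA,3,17.045
P0005,CST3,1,7.717
P0005,CST3,2,7.817
P0005,CST3,3,7.663
P0005,PTEN,1,35.051
P0005,PTEN,2,35.075
P0005,PTEN,3,35.056
P0005,PIP5K1A,1,34.09
P0005,PIP5K1A,2,33.978
P0005,PIP5K1A,3,34.075
P0005,CDK1,1,22.589
P0005,CDK1,2,23.052
P0005,CDK1,3,22.935
P0005,TMPRSS2,1,32.081
P0005,TMPRSS2,2,31.786
P0005,TMPRSS2,3,32.21
P0005,ANXA3,1,32.146
P0005,ANXA3,2,32.357
P0005,ANXA3,3,32.575
P0005,CCND1,1,12.849
P0005,CCND1,2,12.808
P0005,CCND1,3,12.839
P0005,ACTB,1,25.436
P0005,ACTB,2,25.144
P0005,ACTB,3,25.24
P0006,PMP22,1,17.581
P0006,PMP22,2,17.651
P0006,PMP22,3,17.559
P0006,GOLM1,1,16.289
P0006,GOLM1,2,15.981
P0006,GOLM1,3,16.167
P0006,LMTK2,1,15.478
P0006,LMTK2,2,15.43
P0006,LMTK2,3,15.239
P0006,EZH2,1,30.15
P0006,EZH2,2,30.224
P0006,EZH2,3,30.343
P0006,GSTP1,1,23.264
P0006,GSTP1,2,23.37
P0006,GSTP1,3,23.256
P0006,PCA3,1,22.776
P0006,PCA3,2,23.16
P0006,PCA3,3,23.162
P0006,VEGFA,1,15.799
P0006,VEGFA,2,15.805
P0006,VEGFA,3,16.025
P0006,CST3,1,15.584
P0006,CST3,2,15.155
P0006,CST3,3,15.776
P0006,PTEN,1,24.939
P0006,PTEN,2,25.185
P0006,PTEN,3,25.361
P0006,PIP5K1A,1,32.442
P0006,PIP5K1A,2,32.26
P0006,PIP5K1A,3,32.249
P0006,CDK1,1,30.229
P0006,CDK1,2,30.342
P0006,CDK1,3,30.149
P0006,TMPRSS2,1,25.226
P0006,TMPRSS2,2,25.596
P0006,TMPRSS2,3,25.723
P0006,ANXA3,1,23.843
P0006,ANXA3,2,24.034
P0006,ANXA3,3,23.852
P0006,CCND1,1,11.216
P0006,CCND1,2,11.288
P0006,CCND1,3,11.165
P0006,ACTB,1,25.993
P0006,ACTB,2,26.013
P0006,ACTB,3,26.009
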