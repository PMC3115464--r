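condition,weight,icd9_prefix
mi,1,410
mi,1,412
chf,1,39891
chf,1,40201
chf,1,40211
chf,1,40291
chf,1,40401
chf,1,40403
chf,1,40411
chf,1,40413
chf,1,40491
chf,1,40493
chf,1,4254
chf,1,4255
chf,1,4256
chf,1,4257
chf,1,4258
chf,1,4259
chf,1,428
pvd,1,0930
pvd,1,4373
pvd,1,440
pvd,1,441
pvd,1,4431
pvd,1,4432
pvd,1,4433
pvd,1,4434
pvd,1,4435
pvd,1,4436
pvd,1,4437
pvd,1,4438
pvd,1,4439
pvd,1,4471
pvd,1,5571
pvd,1,5579
pvd,1,V434
cvd,1,36234
cvd,1,430
cvd,1,431
cvd,1,432
cvd,1,433
cvd,1,434
cvd,1,435
cvd,1,436
cvd,1,437
cvd,1,438
dementia,1,290
dementia,1,2941
dementia,1,3312
copd,1,4168
copd,1,4169
copd,1,490
copd,1,491
copd,1,492
copd,1,493
copd,1,494
copd,1,495
copd,1,496
copd,1,497
copd,1,498
copd,1,499
copd,1,500
copd,1,501
copd,1,502
copd,1,503
copd,1,504
copd,1,505
copd,1,5064
copd,1,5081
copd,1,5088
rheum,1,4465
rheum,1,7100
rheum,1,7101
rheum,1,7102
rheum,1,7103
rheum,1,7104
rheum,1,7140
rheum,1,7141
rheum,1,7142
rheum,1,7148
rheum,1,725
pud,1,531
pud,1,532
pud,1,533
pud,1,534
mild_liver,1,07022
mild_liver,1,07023
mild_liver,1,07032
mild_liver,1,07033
mild_liver,1,07044
mild_liver,1,07054
mild_liver,1,0706
mild_liver,1,0709
mild_liver,1,570
mild_liver,1,571
mild_liver,1,5733
mild_liver,1,5734
mild_liver,1,5738
mild_liver,1,5739
mild_liver,1,V427
diab_unc,1,2500
diab_unc,1,2501
diab_unc,1,2502
diab_unc,1,2503
diab_unc,1,2508
diab_unc,1,2509
diab_comp,2,2504
diab_comp,2,2505
diab_comp,2,2506
diab_comp,2,2507
paralysis,2,3341
paralysis,2,342
paralysis,2,343
paralysis,2,3440
paralysis,2,3441
paralysis,2,3442
paralysis,2,3443
paralysis,2,3444
paralysis,2,3445
paralysis,2,3446
paralysis,2,3449
renal,2,40301
renal,2,40311
renal,2,40391
renal,2,40402
renal,2,40403
renal,2,40412
renal,2,40413
renal,2,40492
renal,2,40493
renal,2,582
renal,2,5830
renal,2,5831
renal,2,5832
renal,2,5833
renal,2,5834
renal,2,5835
renal,2,5836
renal,2,5837
renal,2,585
renal,2,586
renal,2,5880
renal,2,V420
renal,2,V451
renal,2,V56
malignancy,2,140
malignancy,2,141
malignancy,2,142
malignancy,2,143
malignancy,2,144
malignancy,2,145
malignancy,2,146
malignancy,2,147
malignancy,2,148
malignancy,2,149
malignancy,2,150
malignancy,2,151
malignancy,2,152
malignancy,2,153
malignancy,2,154
malignancy,2,155
malignancy,2,156
malignancy,2,157
malignancy,2,158
malignancy,2,159
malignancy,2,160
malignancy,2,161
malignancy,2,162
malignancy,2,163
malignancy,2,164
malignancy,2,165
malignancy,2,166
malignancy,2,167
malignancy,2,168
malignancy,2,169
malignancy,2,170
malignancy,2,171
malignancy,2,172
malignancy,2,174
malignancy,2,175
malignancy,2,176
malignancy,2,179
malignancy,2,180
malignancy,2,181
malignancy,2,182
malignancy,2,183
malignancy,2,184
malignancy,2,185
malignancy,2,186
malignancy,2,187
malignancy,2,188
malignancy,2,189
malignancy,2,190
malignancy,2,191
malignancy,2,192
malignancy,2,193
malignancy,2,194
malignancy,2,195
malignancy,2,200
malignancy,2,201
malignancy,2,202
malignancy,2,203
malignancy,2,204
malignancy,2,205
malignancy,2,206
malignancy,2,207
malignancy,2,208
malignancy,2,2386
sev_liver,3,4560
sev_liver,3,4561
sev_liver,3,4562
sev_liver,3,5722
sev_liver,3,5723
sev_liver,3,5724
sev_liver,3,5725
sev_liver,3,5726
sev_liver,3,5727
sev_liver,3,5728
mets,6,196
mets,6,197
mets,6,198
mets,6,199
aids,6,042
aids,6,043
aids,6,044
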