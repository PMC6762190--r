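# synthetic two-subject example cohort (generated with generate_cohort, master seed 2026)
subject_id,modality,level,x_mm,y_mm
S01,mri_spinous,T1,420,0
S01,mri_spinous,T2,399.8076923076923,5.594451661090583
S01,mri_spinous,T3,378.8076923076923,11.107792658847588
S01,mri_spinous,T4,357,16.18465711954569
S01,mri_spinous,T5,334.38461538461536,20.435558463972292
S01,mri_spinous,T6,310.96153846153845,23.466479118678762
S01,mri_spinous,T7,286.7307692307692,24.917529739005566
S01,mri_spinous,T8,261.6923076923077,24.508562132229507
S01,mri_spinous,T9,235.84615384615384,22.087801111150572
S01,mri_spinous,T10,209.19230769230768,17.67766952966369
S01,mri_spinous,T11,181.73076923076923,11.510337493623407
S01,mri_spinous,T12,153.46153846153845,4.044549913819128
S01,mri_spinous,L1,124.38461538461536,-6.457608095428927
S01,mri_spinous,L2,94.5,-16.878724471214134
S01,mri_spinous,L3,63.80769230769232,-19.83675223950446
S01,mri_spinous,L4,32.30769230769232,-13.346376224444796
S01,mri_spinous,L5,0,-2.4492935982947065e-15
S01,mri_fiducial,T1,423.31291097261635,12.387434607084689
S01,mri_fiducial,T2,403.7286234279566,18.267553012747417
S01,mri_fiducial,T3,382.2024694838037,23.952751789262017
S01,mri_fiducial,T4,359.5123023876298,29.17363817780391
S01,mri_fiducial,T5,335.4695900002974,33.9868462565044
S01,mri_fiducial,T6,312.3526352069771,37.64717782372581
S01,mri_fiducial,T7,286.4210671200336,38.453252865685286
S01,mri_fiducial,T8,260.27235322087415,37.7890670592724
S01,mri_fiducial,T9,234.589324045091,36.152550320675886
S01,mri_fiducial,T10,207.13627603984082,30.54986685585297
S01,mri_fiducial,T11,177.9466319598559,25.808213242473897
S01,mri_fiducial,T12,149.24758791152257,17.494284708122517
S01,mri_fiducial,L1,119.54515448039018,6.110770473186352
S01,mri_fiducial,L2,90.68865231733895,-2.8453905877851393
S01,mri_fiducial,L3,65.301026410924365,-4.202300259697761
S01,mri_fiducial,L4,37.387017786302536,6.127130192829412
S01,mri_fiducial,L5,8.144655421721144,19.75956502970257
S01,dss_surface,T1,421.7922115446487,0.5984520303165137
S01,dss_surface,T2,400.12095944438903,6.975280694524821
S01,dss_surface,T3,379.4516950139379,12.572777736347536
S01,dss_surface,T4,358.17943119362894,16.72466081937462
S01,dss_surface,T5,334.15182230914087,20.33252541927555
S01,dss_surface,T6,310.364171492323,24.882323698948714
S01,dss_surface,T7,284.3910438280774,27.136203875068137
S01,dss_surface,T8,259.3638567567966,26.469981220574777
S01,dss_surface,T9,233.10444593134434,24.108797561332775
S01,dss_surface,T10,205.93636733617257,19.561453731653753
S01,dss_surface,T11,177.8371269838454,14.602271177621468
S01,dss_surface,T12,149.3017675070779,7.291264904882228
S01,dss_surface,L1,119.39970541191896,-2.444863833424721
S01,dss_surface,L2,90.50927412501099,-13.362072603771665
S01,dss_surface,L3,63.10908545570724,-12.906130404986992
S01,dss_surface,L4,34.6159673227266,-3.71989492441144
S01,dss_surface,L5,5.369651583589136,13.27092460296948
S02,mri_spinous,T1,420,0
S02,mri_spinous,T2,399.8076923076923,5.594451661090583
S02,mri_spinous,T3,378.8076923076923,11.107792658847588
S02,mri_spinous,T4,357,16.18465711954569
S02,mri_spinous,T5,334.38461538461536,20.435558463972292
S02,mri_spinous,T6,310.96153846153845,23.466479118678762
S02,mri_spinous,T7,286.7307692307692,24.917529739005566
S02,mri_spinous,T8,261.6923076923077,24.508562132229507
S02,mri_spinous,T9,235.84615384615384,22.087801111150572
S02,mri_spinous,T10,209.19230769230768,17.67766952966369
S02,mri_spinous,T11,181.73076923076923,11.510337493623407
S02,mri_spinous,T12,153.46153846153845,4.044549913819128
S02,mri_spinous,L1,124.38461538461536,-6.457608095428927
S02,mri_spinous,L2,94.5,-16.878724471214134
S02,mri_spinous,L3,63.80769230769232,-19.83675223950446
S02,mri_spinous,L4,32.30769230769232,-13.346376224444796
S02,mri_spinous,L5,0,-2.4492935982947065e-15
S02,mri_fiducial,T1,425.733452362963,17.69248081381721
S02,mri_fiducial,T2,404.7388671157933,23.78276886636452
S02,mri_fiducial,T3,383.2620812720238,28.649330977914857
S02,mri_fiducial,T4,360.9031639798582,34.650999203948395
S02,mri_fiducial,T5,336.9485289519815,39.04903578947482
S02,mri_fiducial,T6,311.8662972807247,42.30904172907231
S02,mri_fiducial,T7,287.4459789162538,42.445684680801705
S02,mri_fiducial,T8,261.7474654869763,43.42549149758856
S02,mri_fiducial,T9,233.79145610109435,40.8399632700886
S02,mri_fiducial,T10,206.09494086533945,35.70440224389797
S02,mri_fiducial,T11,176.61902218012943,29.54770009970922
S02,mri_fiducial,T12,147.45782256345444,22.013947083107357
S02,mri_fiducial,L1,118.93978557962139,11.738473730015448
S02,mri_fiducial,L2,91.38134564338358,2.485487953964316
S02,mri_fiducial,L3,65.37811094448274,5.753213906942541
S02,mri_fiducial,L4,42.81375984508991,18.881086196625407
S02,mri_fiducial,L5,15.655351874853398,38.2692770772224
S02,dss_surface,T1,422.9984074003128,9.845612165691637
S02,dss_surface,T2,403.08151276299856,14.652237947333576
S02,dss_surface,T3,382.9322930547465,20.563028926536518
S02,dss_surface,T4,359.5933839102776,25.90049707176054
S02,dss_surface,T5,336.20264544307605,29.56572401642319
S02,dss_surface,T6,312.3684874631384,32.50281301505531
S02,dss_surface,T7,286.34751167172345,33.94685594750889
S02,dss_surface,T8,260.6447961241841,32.74998708437671
S02,dss_surface,T9,232.6778358395837,30.516058149598983
S02,dss_surface,T10,206.78461306171673,26.601762802625466
S02,dss_surface,T11,178.53706292531965,20.39394769094921
S02,dss_surface,T12,149.49453669417875,11.850747534907919
S02,dss_surface,L1,119.68762939204683,0.7640204536913995
S02,dss_surface,L2,91.91988500691969,-7.26356899751889
S02,dss_surface,L3,64.86764929572178,-5.733432631039806
S02,dss_surface,L4,40.332716027940194,9.435587168603316
S02,dss_surface,L5,13.138392045547219,26.70084123479267
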