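stage,epoch,loss
finetune,0,0.7622985077
finetune,1,0.8134748423
finetune,2,0.7831981095
finetune,3,0.7805660484
finetune,4,0.7705302131
finetune,5,0.7586850577
finetune,6,0.7649427731
finetune,7,0.7588139489
finetune,8,0.7544179922
finetune,9,0.7503310844
finetune,10,0.7470285132
finetune,11,0.7440194774
finetune,12,0.7417128502
finetune,13,0.7392644163
finetune,14,0.7362938744
finetune,15,0.7343543548
finetune,16,0.7324002687
finetune,17,0.7303773779
finetune,18,0.728280392
finetune,19,0.7263474589
finetune,20,0.7243986339
retrain,0,0.7622985077
retrain,1,0.8134748423
retrain,2,0.7831981095
retrain,3,0.7805660484
retrain,4,0.7705302131
retrain,5,0.7586850577
retrain,6,0.7649427731
retrain,7,0.7588139489
retrain,8,0.7544179922
retrain,9,0.7503310844
retrain,10,0.7470285132
retrain,11,0.7440194774
retrain,12,0.7417128502
retrain,13,0.7392644163
retrain,14,0.7362938744
retrain,15,0.7343543548
retrain,16,0.7324002687
retrain,17,0.7303773779
retrain,18,0.728280392
retrain,19,0.7263474589
retrain,20,0.7243986339
retrain,21,0.7226166545
retrain,22,0.721090372
retrain,23,0.7196403284
retrain,24,0.7179710575
retrain,25,0.7163707623
retrain,26,0.7148637045
retrain,27,0.7141119473
retrain,28,0.7120638987
retrain,29,0.7107332194
retrain,30,0.7093662841
retrain,31,0.7080436301
retrain,32,0.7079116155
retrain,33,0.7058204947
retrain,34,0.705708333
retrain,35,0.7035442917
retrain,36,0.7033689065
retrain,37,0.7009178046
retrain,38,0.6997345534
retrain,39,0.6999719223
retrain,40,0.6975593825
retrain,41,0.6976048552
retrain,42,0.6965332896
retrain,43,0.6942889098
retrain,44,0.6944425879
retrain,45,0.6932538626
retrain,46,0.6922008052
retrain,47,0.6911359591
retrain,48,0.6889175945
retrain,49,0.6892690795
retrain,50,0.6871844501
retrain,51,0.6875105654
retrain,52,0.6863577154
retrain,53,0.6853663423
retrain,54,0.6843397392
retrain,55,0.6834196659
retrain,56,0.6825581023
retrain,57,0.681743587
retrain,58,0.6809887171
retrain,59,0.6801642433
retrain,60,0.6790290982
retrain,61,0.6780955234
retrain,62,0.6773104732
retrain,63,0.6763440088
retrain,64,0.6755725093
retrain,65,0.6750305261
retrain,66,0.6747031302
retrain,67,0.6740549272
retrain,68,0.6730221957
retrain,69,0.6720251912
retrain,70,0.6710289995
retrain,71,0.6704068963
retrain,72,0.6698472789
retrain,73,0.6692180031
retrain,74,0.6682088315
retrain,75,0.6673035579
retrain,76,0.6665979609
retrain,77,0.6660423296
retrain,78,0.6654473056
retrain,79,0.6645201801
retrain,80,0.6638703204
retrain,81,0.663479534
retrain,82,0.6628607924
retrain,83,0.6620346385
retrain,84,0.6612192532
retrain,85,0.6607278302
retrain,86,0.6603376459
retrain,87,0.6597984189
retrain,88,0.6591407555
retrain,89,0.6583661957
retrain,90,0.6578048456
retrain,91,0.6574289037
retrain,92,0.6569126549
retrain,93,0.6562118333
retrain,94,0.6555475771
retrain,95,0.6550140453
retrain,96,0.6546279983
retrain,97,0.6540722147
retrain,98,0.6535787598
retrain,99,0.6529520869
retrain,100,0.6524229599
retrain,101,0.6519363385
retrain,102,0.6514704188
retrain,103,0.6514714451
retrain,104,0.6513252068
retrain,105,0.6503674164
retrain,106,0.6497038419
retrain,107,0.6495211734
retrain,108,0.6491268962
retrain,109,0.6484839535
retrain,110,0.6482652416
retrain,111,0.6478334916
retrain,112,0.6470465106
retrain,113,0.6467831032
retrain,114,0.6466637304
retrain,115,0.645772076
retrain,116,0.6453186617
retrain,117,0.645110296
retrain,118,0.644669421
retrain,119,0.644127593
retrain,120,0.6437344216
retrain,121,0.6432920868
retrain,122,0.6430108689
retrain,123,0.6426073419
retrain,124,0.6424826964
retrain,125,0.6427845103
retrain,126,0.6419358673
retrain,127,0.6411404448
retrain,128,0.6413703921
retrain,129,0.6413711178
retrain,130,0.640666315
retrain,131,0.6399106093
retrain,132,0.6481649508
retrain,133,0.6391793425
retrain,134,0.6392292394
retrain,135,0.6470260846
retrain,136,0.6466850874
retrain,137,0.6460745951
retrain,138,0.6460345637
retrain,139,0.6453704854
retrain,140,0.6455385586
retrain,141,0.6447925178
retrain,142,0.6445232995
retrain,143,0.6439851598
retrain,144,0.6439253246
retrain,145,0.6434324289
retrain,146,0.6431317661
retrain,147,0.6428288605
retrain,148,0.6425480423
retrain,149,0.6420913925
retrain,150,0.6418747815
retrain,151,0.6416303612
retrain,152,0.6413877176
retrain,153,0.6411992825
retrain,154,0.6406146443
retrain,155,0.6405411491
retrain,156,0.6401380267
retrain,157,0.6400501897
retrain,158,0.6399774941
retrain,159,0.6395884825
retrain,160,0.6393492506
retrain,161,0.6388128874
retrain,162,0.6388784638
retrain,163,0.6383839186
retrain,164,0.6383912671
retrain,165,0.6378391637
retrain,166,0.6375637924
retrain,167,0.6372669329
retrain,168,0.6369436376
retrain,169,0.6367884251
retrain,170,0.6367351951
retrain,171,0.636617858
retrain,172,0.6362445162
retrain,173,0.635721688
retrain,174,0.6353982045
retrain,175,0.6350859443
retrain,176,0.6349435871
retrain,177,0.6348720249
retrain,178,0.635512136
retrain,179,0.6348490354
retrain,180,0.634271512
retrain,181,0.6338104356
retrain,182,0.6335052551
retrain,183,0.6333484079
retrain,184,0.6332718901
retrain,185,0.6336003535
retrain,186,0.6328121218
retrain,187,0.6323372917
retrain,188,0.6323652779
retrain,189,0.6322155463
retrain,190,0.6320212897
retrain,191,0.6315444047
retrain,192,0.6315090214
retrain,193,0.6317999529
retrain,194,0.631077205
retrain,195,0.6308428179
retrain,196,0.6308907553
retrain,197,0.6307132403
retrain,198,0.6305326993
retrain,199,0.6313036158
retrain,200,0.6298350174
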