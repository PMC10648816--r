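id,group,age,sex,bmi,ac,bscd,ls,pdff
NAFLD-001,NAFLD,18,M,33.7934818790041,1.21648925468948,114.379482558785,5.36340260484074,45.282765151827
NAFLD-002,NAFLD,70,M,34.1874640723686,0.714703662973211,82.9135547272584,4.53352069827539,0
NAFLD-003,NAFLD,54,M,31.0450160083496,0.866910606127785,105.484630344816,3.4185600354252,16.6097810893116
NAFLD-004,NAFLD,64,M,22.189725018793,0.581093534721685,88.8691728709785,6.81648512143323,0
NAFLD-005,NAFLD,50,F,31.0912511681006,0.716147103847727,95.3606895088762,4.35627720238043,0.456150937333184
NAFLD-006,NAFLD,41,M,29.7684478965455,0.883370892539166,99.0643422651584,7.64257576598173,9.18271316734439
NAFLD-007,NAFLD,69,F,21.8074895735866,0.812068533513225,93.849582213794,2.75944496627169,3.1760375366566
NAFLD-008,NAFLD,39,M,25.9147056109973,0.68301988693495,94.1766474395631,4.81053613717636,0.815396125356572
NAFLD-009,NAFLD,58,F,33.6223468440084,0.878513092118159,118.688053925987,7.22504825940281,20.2609372447842
NAFLD-010,NAFLD,49,F,37.5094254531916,1.00964344528679,111.406087443801,2.68676212826502,16.9835764573581
NAFLD-011,NAFLD,75,F,30.8634069552304,0.552068049313559,80.9789329458613,9.3868294570072,11.8761184984072
NAFLD-012,NAFLD,79,F,35.2052749870253,0.811203007127984,104.112626227679,8.5114141669767,19.3297451109984
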