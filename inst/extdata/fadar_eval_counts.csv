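station,classifier,sample_size,n,TP,TN,FP,FN,act_pres,act_abs,pred_pres,pred_abs
LS1,FADAR,294,317,64,215,1,37,101,216,65,252
ST2,FADAR,200,185,15,76,0,94,109,76,15,170
ST2,HUMAN,200,271,131,96,17,27,158,113,148,123
ST4,FADAR,200,275,5,161,0,109,114,161,5,270
ST4,HUMAN,200,309,173,87,9,40,213,96,182,127
LS5,FADAR,200,337,204,80,10,48,252,90,214,128
ST6,FADAR,235,307,90,170,3,44,134,173,93,214
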