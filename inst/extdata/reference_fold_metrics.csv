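fold,train_acc,train_f1,acc,prec,rec,f1,auc
1,96.8,94.5,89.3,85.0,77.6,81.1,0.940
2,95.1,91.8,85.0,75.0,72.3,73.6,0.882
3,96.5,94.0,89.0,86.1,76.3,80.9,0.916
4,95.8,92.7,92.2,86.1,87.7,86.9,0.968
5,97.5,95.6,90.1,86.7,79.6,83.0,0.935
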