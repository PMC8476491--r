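metric	value
n_pos	1709
n_neg	1709
roc_auc	0.883
pr_auc	0.878
accuracy	0.787
mcc	0.585
precision	0.739
specificity	0.686
sensitivity	0.887
f_score	0.806
npv	0.859
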