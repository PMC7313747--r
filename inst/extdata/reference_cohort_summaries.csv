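metric,true_mean,removal_mean,n_participants
tdee,2626.59,2283.15,109
steps,10570.34,9249.6,109
sedentary,1087.76,956.05,109
light,266.77,235.5,109
moderate,50.24,44.63,109
vigorous,7.29,6.51,109
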