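subject_id,hippocampus,csf_tau,fdg_pet,memory
subj0001,2.5071426191576336,2.6642928034500803,2.313095831583476,3.5269771935981939
subj0002,0.65794055690921605,,-0.2471161348763864,1.373546006716184
subj0003,0.2098636416161116,-0.14487409503847259,2.7769865145822399,
subj0004,4.7458752533861555,,3.6745653212799931,5.56043778500438
subj0005,2.4581085652205137,3.5089137648331508,3.1256234449761333,4.5656361342695231
subj0006,-0.33595032815432674,0.733555002785229,1.4450221495054525,2.5681961633451955
subj0007,3.4166350422465195,,2.7648784503932902,4.5876629611818185
subj0008,2.4831999344883506,3.2803604441490757,1.3682376716257054,2.8823828114191912
subj0009,1.1843843569264159,1.265375104002473,0.78958305046157551,4.1662657124807012
subj0010,0.1631156142782304,3.3856144738457368,,2.6348475391261847
subj0011,-0.115713962254788,0.00020566114192949181,0.5670626508955805,1.0198382601831186
subj0012,0.97979451529270323,3.728636509004478,4.329983633569916,
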