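source,raw_label,label
physionet,normal,normal
physionet,abnormal,abnormal
pascal,normal,normal
pascal,murmur,abnormal
pascal,extrahs,abnormal
pascal,extrastole,abnormal
pascal,artifact,noise
yaseen,N,normal
yaseen,AS,abnormal
yaseen,MS,abnormal
yaseen,MR,abnormal
yaseen,MVP,abnormal
synthetic,normal,normal
synthetic,abnormal,abnormal
synthetic,noise,noise
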