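file,md5
market_features.csv,7a20a758aa7cba42040af5b4183880b9
market_conditions.csv,2b688ff64ee8084df32f668d056bab9e
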