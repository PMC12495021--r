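stimulus,density,char_path_length,global_efficiency,global_clustering
1,0.0874,3.1634,0.2456,0.2276
2,0.0764,2.7747,0.1871,0.2213
3,0.1170,2.8137,0.3428,0.3749
4,0.0874,3.1204,0.2278,0.2408
5,0.1429,2.3377,0.4041,0.2715
6,0.0936,3.0560,0.2939,0.2139
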