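accession	five_prime	three_prime	size_bp
OZ251087.1	no short repeat array	123,553,250–123,555,627	123,555,627
OZ251088.1	no short repeat array	115,084,180–115,086,667	115,086,667
OZ251089.1	1–2316	no short repeat array	93,318,919
OZ251090.1	no short repeat array	no short repeat array	61,893,665
OZ251091.1	no short repeat array	54,814,880–54,818,687	54,818,687
OZ251092.1	no short repeat array	no short repeat array	53,992,875
OZ251093.1	no short repeat array	no short repeat array	8,187,640
OZ251094.1	no short repeat array	no short repeat array	24,839,040
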