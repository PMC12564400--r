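accession	five_prime	three_prime	size_bp
OY986040.1	1–8005	150,122,476–150,126,493	150,126,493
OY986041.1	no short repeat array	142,391,635–142,396,179	142,396,181
OY986042.1	1–3300	no short repeat array	119,373,907
OY986043.1	no short repeat array	100,876,893–100,877,120	100,877,120
OY986044.1	1–7554	88,716,705–88,717,929	88,717,929
OY986045.1	no short repeat array	no short repeat array	73,119,431
OY986046.1	no short repeat array	no short repeat array	41,815,626
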