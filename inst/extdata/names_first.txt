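# First names used by the synthetic narrative generator and the
# sensitivity protocol. Mixed origins on purpose, so fairness probes
# (e.g. comparing detection of South Asian vs common English names) are
# expressible. One name per line; all entries longer than 3 characters.
John
Jane
Hanna
Ramesh
Priya
Deirdre
Amara
Fatima
Xiulan
Lars
Sofia
Dmitri
Keiko
Tariq
Aisha
Carlos
Ingrid
Kwame
Meiling
Olusegun
Harpreet
Siobhan
Bridget
Rajesh
Anika
Gareth
Nadia
Piotr
Yusuf
Margaret
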