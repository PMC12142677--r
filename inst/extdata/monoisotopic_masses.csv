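element,mass,version
C,12.0,CODATA-2018
H,1.00782503207,CODATA-2018
N,14.0030740048,CODATA-2018
O,15.9949146196,CODATA-2018
P,30.97376163,CODATA-2018
S,31.97207100,CODATA-2018
Na,22.9897692809,CODATA-2018
K,38.96370668,CODATA-2018
F,18.99840322,CODATA-2018
Cl,34.96885268,CODATA-2018
Br,78.9183371,CODATA-2018
I,126.904473,CODATA-2018
Si,27.9769265325,CODATA-2018
Se,79.9165213,CODATA-2018
B,11.0093054,CODATA-2018
Li,7.01600455,CODATA-2018
Ca,39.96259098,CODATA-2018
Fe,55.9349375,CODATA-2018
Mg,23.9850417,CODATA-2018
Zn,63.9291422,CODATA-2018
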