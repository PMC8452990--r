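key	mass	pka	charge
A	71.0788	NA	
R	156.1875	12.5	+
N	114.1038	NA	
D	115.0886	3.9	-
C	103.1388	8.5	-
E	129.1155	4.1	-
Q	128.1307	NA	
G	57.0519	NA	
H	137.1411	6.5	+
I	113.1594	NA	
L	113.1594	NA	
K	128.1741	10.8	+
M	131.1926	NA	
F	147.1766	NA	
P	97.1167	NA	
S	87.0782	NA	
T	101.1051	NA	
W	186.2132	NA	
Y	163.1760	10.1	-
V	99.1326	NA	
NTERM	NA	8.6	+
CTERM	NA	3.6	-
WATER	18.0153	NA	
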