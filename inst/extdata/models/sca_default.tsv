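# SCA-style sound-class model: coarse phone classes with an
# alignment similarity table and linear gap penalty.
name	sca_default
version	1.0
gap_penalty	-4
unknown_code	?
[mapping]
p	P
b	P
ɓ	P
f	B
v	B
ɸ	B
β	B
t	T
d	T
ʈ	T
ɖ	T
s	S
z	S
ʃ	S
ʒ	S
ʂ	S
ʐ	S
ɕ	S
ʑ	S
θ	S
ð	S
ts	C
dz	C
tʃ	C
dʒ	C
tɕ	C
dʑ	C
ʈʂ	C
ɖʐ	C
pf	C
k	K
g	K
ɡ	K
q	K
ɢ	K
c	K
ɟ	K
x	G
ɣ	G
χ	G
h	G
ɦ	G
ʔ	G
m	N
n	N
ɲ	N
ŋ	N
ɳ	N
ɱ	N
l	L
ʎ	L
ɭ	L
ɫ	L
r	R
ɾ	R
ɽ	R
ʀ	R
ʁ	R
w	W
ʋ	W
ɥ	W
j	J
a	A
ɑ	A
ɐ	A
æ	A
ä	A
e	E
ɛ	E
ə	E
ɜ	E
œ	E
ø	E
ɘ	E
i	I
ɪ	I
y	I
ɨ	I
ʏ	I
o	O
ɔ	O
ɒ	O
ɤ	O
u	U
ʊ	U
ɯ	U
ʉ	U
˥	1
˦	1
˧	1
˨	1
˩	1
[similarity]
.	P	B	T	S	C	K	G	N	L	R	W	J	A	E	I	O	U	1	?
P	10	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
B	4	10	0	0	0	0	0	0	0	0	3	0	0	0	0	0	0	0	0
T	0	0	10	4	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0
S	0	0	4	10	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0
C	0	0	4	6	10	0	0	0	0	0	0	0	0	0	0	0	0	0	0
K	0	0	0	0	0	10	4	0	0	0	0	0	0	0	0	0	0	0	0
G	0	0	0	0	0	4	10	0	0	0	0	0	0	0	0	0	0	0	0
N	0	0	0	0	0	0	0	10	0	0	0	0	0	0	0	0	0	0	0
L	0	0	0	0	0	0	0	0	10	3	0	0	0	0	0	0	0	0	0
R	0	0	0	0	0	0	0	0	3	10	0	0	0	0	0	0	0	0	0
W	0	3	0	0	0	0	0	0	0	0	10	0	0	0	0	0	2	0	0
J	0	0	0	0	0	0	0	0	0	0	0	10	0	0	2	0	0	0	0
A	0	0	0	0	0	0	0	0	0	0	0	0	7	3	3	3	3	0	0
E	0	0	0	0	0	0	0	0	0	0	0	0	3	7	3	3	3	0	0
I	0	0	0	0	0	0	0	0	0	0	0	2	3	3	7	3	3	0	0
O	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	7	3	0	0
U	0	0	0	0	0	0	0	0	0	0	2	0	3	3	3	3	7	0	0
1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	0
?	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
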