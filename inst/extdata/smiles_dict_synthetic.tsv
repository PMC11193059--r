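<MASK>	0
C	1
(	2
)	3
c	4
O	5
1	6
2	7
N	8
n	9
=	10
3	11
[	12
]	13
@	14
H	15
4	16
o	17
S	18
+	19
-	20
F	21
5	22
/	23
s	24
#	25
l	26
\	27
6	28
B	29
r	30
P	31
.	32
7	33
I	34
8	35
9	36
0	37
%	38
e	39
i	40
p	41
Z	42
M	43
g	44
a	45
A	46
K	47
T	48
b	49
t	50
u	51
:	52
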