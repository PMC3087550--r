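pogo_id	is_paralog_group	homolog_group	species
U	no	I	Cp,Mp
V	no	II	Cv,Mp,Pp,Sm,Gm,Pt,Vv,Os,Sb
A	no	I	Mp,Pp,Sm,At,Os
B	no	I	Pp,Sm,At,Gm
C	no	I	Sm,At,Os
D	no	I	At,Gm,Pin
E	no	I	Sm,At,Os
F	no	I	Mp,Pp,Sm,At,Os
G	no	I	Os,Sb
H	no	I	At,Os
I	no	I	At,Os
J	no	I	At,Os
L	no	I	Pp,Tr
M	no	I	At,Os
N	no	I	At,Os,Pin
O	no	I	Mp,Pp,Sm,At
P	no	I	Pin,Pic
Q	no	I	At,Os
R	no	I	Os,Sb
S	no	I	Os,Sb
T	no	I	At,Os
K	yes	I	Pp
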