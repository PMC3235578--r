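id	formula	charge	role
1	C5H10N2O3	0	normal
3	C8H15N3O4	0	normal
5	C11H15N5O	0	normal
Im	C3H4N2	0	normal
NMA	C3H7NO	0	normal
H2O	H2O	0	water
H+	H	1	proton
Cu(H2O)5^2+	CuH10O5	2	normal
Cu(H2O)3^+	CuH6O3	1	normal
Cu(Im)(H2O)4^2+	C3H12CuN2O4	2	normal
Cu(Im)2(H2O)3^2+	C6H14CuN4O3	2	normal
Cu(Im)(H2O)+	C3H6CuN2O	1	normal
Cu(Im)2+	C6H8CuN4	1	normal
Cu(Im)(H13H14)+	C14H19CuN7O	1	normal
Cu(Im)(H14H13)+	C14H19CuN7O	1	normal
2a(H2O)2	C5H13CuN2O5	1	normal
2b(H2O)2	C5H13CuN2O5	1	normal
2c(H2O)2	C5H13CuN2O5	1	normal
2a(Im)(H2O)	C8H15CuN4O4	1	normal
2a(Im)2	C11H17CuN6O3	1	normal
4(H2O)	C8H16CuN3O5	1	normal
4(Im)	C11H18CuN5O4	1	normal
4(Im)2	C14H22CuN7O4	1	normal
6(H2O)2	C11H19CuN5O3	2	normal
6(Im)(H2O)	C14H21CuN7O2	2	normal
7	C17H26CuN8O2	2	normal
8a	C16H24CuN7O4	1	normal
9	C19H28CuN9O4	1	normal
2I(H2O)	C5H11CuN2O4	0	normal
2aI(H2O)	C5H11CuN2O4	0	normal
2I(Im)	C8H13CuN4O3	0	normal
2I(Im)2	C11H17CuN6O3	0	normal
6I	C11H15CuN5O	1	normal
6I(Im)	C14H19CuN7O	1	normal
7I	C14H22CuN6O2	1	normal
8aI	C16H24CuN7O4	0	normal
8bI	C16H24CuN7O4	0	normal
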