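>SM001	7
0.940000	0.020000	0.020000	0.020000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.940000	0.020000	0.020000	0.020000
>SM002	7
0.940000	0.020000	0.020000	0.020000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
0.940000	0.020000	0.020000	0.020000
>SM003	6
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.940000	0.020000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.940000	0.020000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.940000	0.020000
>SM004	7
0.020000	0.020000	0.940000	0.020000
0.020000	0.020000	0.940000	0.020000
0.940000	0.020000	0.020000	0.020000
0.020000	0.020000	0.940000	0.020000
0.020000	0.020000	0.940000	0.020000
0.940000	0.020000	0.020000	0.020000
0.020000	0.020000	0.940000	0.020000
>SM005	5
0.020000	0.020000	0.020000	0.940000
0.020000	0.940000	0.020000	0.020000
0.940000	0.020000	0.020000	0.020000
0.020000	0.020000	0.020000	0.940000
0.020000	0.020000	0.020000	0.940000
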