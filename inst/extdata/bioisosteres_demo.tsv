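# Curated demo table of classic medicinal-chemistry bioisostere pairs
# (synthetic frequencies for ranking).  Schema matches full database
# exports: fragment <TAB> replacement <TAB> frequency, with [n*]
# attachment-point labels.
fragment	replacement	frequency
[1*]C(=O)O	[1*]c1nnn[nH]1	1000
[1*]C(=O)O	[1*]S(O)(=O)=O	900
[1*]C(=O)O	[1*]C(=O)NO	800
[1*]C(=O)O	[1*]P(=O)(O)O	700
[1*]C(=O)O	[1*]C(=O)NS(C)(=O)=O	600
[1*]C(=O)O	[1*]C(N)=O	500
[1*]C(=O)O	[1*]S(N)(=O)=O	400
[1*]c1ccccc1	[1*]c1ccncc1	1000
[1*]c1ccccc1	[1*]c1cccs1	900
[1*]c1ccccc1	[1*]c1ccco1	800
[1*]c1ccccc1	[1*]c1ccc(F)cc1	700
[1*]c1ccccc1	[1*]C1CCCCC1	600
[1*]C(N)=O	[1*]C(=O)NC	1000
[1*]C(N)=O	[1*]S(N)(=O)=O	900
[1*]C(N)=O	[1*]C#N	800
[1*]C(C)=O	[1*]C(=O)OC	500
[1*]C(C)=O	[1*]S(C)(=O)=O	400
[1*]C(C)=O	[1*]C(F)(F)F	300
[1*]OC	[1*]SC	600
[1*]OC	[1*]CC	500
[1*]OC	[1*]OCC	400
[1*]NC	[1*]OC	300
[1*]NC	[1*]N(C)C	250
[1*]SC	[1*]OC	500
[1*]SC	[1*]S(C)(=O)=O	200
[1*]C#N	[1*]C(N)=O	400
[1*]C#N	[1*]c1nnn[nH]1	300
[1*]c1ccncc1	[1*]c1ccccc1	600
[1*]c1ccncc1	[1*]c1cncnc1	500
[1*]c1cccs1	[1*]c1ccccc1	500
[1*]c1cccs1	[1*]c1ccco1	400
[1*]N1CCOCC1	[1*]N1CCCCC1	800
[1*]N1CCOCC1	[1*]N1CCN(C)CC1	700
[1*]N1CCCCC1	[1*]N1CCOCC1	600
[1*]N1CCCCC1	[1*]N1CCCC1	500
[1*]C1CCCCC1	[1*]C1CCOCC1	400
[1*]C1CCCCC1	[1*]c1ccccc1	300
[1*]O[2*]	[1*]S[2*]	500
[1*]O[2*]	[1*]C[2*]	400
[1*]O[2*]	[1*]N[2*]	300
[1*]N[2*]	[1*]O[2*]	400
[1*]N[2*]	[1*]C[2*]	300
[1*]CC[2*]	[1*]CCC[2*]	200
[1*]C([2*])=O	[1*]S([2*])(=O)=O	600
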