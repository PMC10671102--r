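root
	H2a2a1	263A! 750A! 8860A! 15326A!
	H	263G 750G 8860G 15326G
		H2a	951A
			H2a1n	146C 4659A 16354T
		H1	3010A
			H1b	16356C
		H6c	16482G
	R	73G 263G 750G 1438G 2706G 4769G 7028T 8860G 11719A 14766T 15326G
		U	11467G 12308G 12372A
			U5	3197C 9477A 13617C 16270T
				U5b	150T 7768G 14182C
					U5b1	5656G
						U5b1b	7385G
							U5b1b1a	10927C 12618A 16144C 16189C
			U8	282C 1811G 9698C
				U8a1a1a	3738T 4129G 5240G 6392C 6455T 7055G 9365T 10733T 11150A 12135A 13145A 16209C 16342C
			K	1189C 10550G 11299C 14798C 16224C 16311C
		T	709A 1888A 4917G 8697A 10463C 13368A 14905A 15607G 16126C 16294T
			T2	11812G 16296T
		J	295T 489C 10398G 12612G 13708A 16069T 16126C
			J1	462T 3010A
		V	4580A 15904T 16298C
		W	1243C 5460A 8251A 8994A 11947G 15884C 16292T
			W1a	16320T
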