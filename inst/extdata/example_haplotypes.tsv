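EX001	mitogenome	146C 263G 309.xC 315.1C 750G 951A 4659A 8860G 15326G 16354T
EX002	mitogenome	73G 263G 282C 309.1C 315.1C 750G 1438G 1811G 2706G 3738T 4129G 4769G 5240G 6392C 6455T 7028T 7055G 8860G 9365T 9698C 10733T 11150A 11467G 11719A 12135A 12308G 12372A 13145A 14766T 15326G 16209C 16342C
EX003	mitogenome	73G 150T 263G 309.xC 315.1C 750G 1438G 2706G 3197C 4769G 5656G 7028T 7385G 7768G 8860G 9477A 10927C 11467G 11719A 12308G 12372A 12618A 13617C 14182C 14766T 15326G 16144C 16189C 16270T
EX004	mitogenome	
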