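accession_id	western	eastern	classic	non_irrigated
G1_IRR_001	0.0563166641738092	0.00920068580455497	0.922729653685837	0.0117529963357989
G1_IRR_002	0.98399779321415	0.00173083407926431	0.00519218875315792	0.00907918395342775
G1_IRR_003	0.0291062802958883	0.907454726374002	0.0380265623927979	0.0254124309373119
G1_IRR_004	0.825949484975334	0.000438729352503775	0.0636549994322866	0.109956786239875
G1_IRR_005	0.00487096599047704	0.0232338275310794	0.971879181087006	1.6025391437516e-05
G1_NIR_001	0.080860596798265	0.0121256221611987	0.0546816269632579	0.852332154077278
G1_NIR_002	0.00121338253791805	0.00598419383550103	0.00668778594912561	0.986114637677455
G2_IRR_001	0.288236946433894	0.00733322287323231	0.693345287452667	0.0110845432402061
G2_IRR_002	0.146553956212186	0.0152835252021559	0.832612234269837	0.00555028431582181
G2_IRR_003	0.0434552396279761	0.0127089712361861	0.935017035536129	0.00881875359970855
G2_IRR_004	0.565275874713168	0.00850717964071009	0.418902211511497	0.00731473413462478
G3_IRR_001	0.304365557170572	0.0106080754384481	0.676959623523813	0.00806674386716667
G3_IRR_002	0.173910398399274	0.0116585233373171	0.805988329529971	0.00844274873343761
G3_IRR_003	0.14129660870645	0.0119211353120343	0.838245506031511	0.00853674995000534
G3_IRR_004	0.304365557170572	0.0106080754384481	0.676959623523813	0.00806674386716667
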