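# Prescribed herbal materials of Yougui Wan (YGW) and their source species.
preparation	phm	phs	processed
YGW	Aconitum carmichaelii Debx	Aconitum carmichaeli	FALSE
YGW	Angelica sinensis (Oliv.) Diels	Angelica sinensis	FALSE
YGW	Cinnamomum cassia Presl	Cinnamomum cassia	FALSE
YGW	Cornus officinalis Sieb. et Zucc	Cornus officinalis	FALSE
YGW	Cuscuta australis R. Br	Cuscuta australis;Cuscuta chinensis	FALSE
YGW	Dioscorea opposita Thunb	Dioscorea opposita	FALSE
YGW	Eucommia ulmoides Oliv	Eucommia ulmoides	FALSE
YGW	Lycium barbarum L.	Lycium barbarum	FALSE
YGW	Rehmanniae radix praeparata	Rehmannia glutinosa	TRUE
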