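# Toy SYNTHETIC accessibility-class map illustrating the file format
# (1-based closed intervals on the map reference; classes I..VI, I = brightest).
# These are NOT published brightness-class values.
start	end	class
1	120	II
121	300	I
301	640	IV
641	700	I
701	1200	III
1201	1400	II
1401	1620	VI
1621	1700	II
1701	1800	V
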