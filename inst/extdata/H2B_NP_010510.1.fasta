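>NP_010510.1 histone H2B [Saccharomyces cerevisiae S288C]
MSAKAEKKPASKAPAEKKPAAKKTSTSTDGKKRSKARKETYSSYIYKVLKQTHPDTGISQKSMSILNSFV
NDIFERIATEASKLAAYNKKSTISAREIQTAVRLILPGELAKHAVSEGTRAVTKYSSSTQA
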