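sample	insert	backbone	other
C1	76186037	1510889	1949870
C2	87051757	1023374	1470027
C3	111161460	1221212	2852606
C4	89858997	728407	2257822
C5	83499317	684081	2568281
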