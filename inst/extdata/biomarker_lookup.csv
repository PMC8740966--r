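wavenumber,assignment,reference
1743.65,Ester carbonyl group C=O of triglycerides,Smith et al.
1681.93,Succinic acid (pure solid form) / Amide I beta-turns,Krimm & Bandekar; Louati et al.
1639.49,Amide I,Movasaghi et al.
1573.91,C=N adenine,Movasaghi et al.
1485.19,C8-H coupled with a ring vibration of guanine,Movasaghi et al.
1442.75,delta(CH) of pectin,Szymanska-Chargot & Zdunek
1396.46,Symmetric CH3 bending of the methyl groups of proteins,Movasaghi et al.
1338.6,In-plane C-O stretching vibration combined with the ring stretch of phenyl,Movasaghi et al.
1141.86,Phosphate and oligosaccharides; oligosaccharide C-O bond in hydroxyl group,Movasaghi et al.
1033.84,Glucomannan,Chylinska et al.
945.119,Xyloglucan,Kacurakova et al.
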