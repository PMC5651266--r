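label,x,y,z
Cz,0,0,9
Fz,0,5.2901,7.2812
Pz,0,-5.2901,7.2812
Fpz,0,8.5595,2.7812
Oz,0,-8.5595,2.7812
C3,-5.2901,0,7.2812
C4,5.2901,0,7.2812
T7,-8.5595,0,2.7812
T8,8.5595,0,2.7812
F3,-5.358,4.4959,5.6639
F4,5.358,4.4959,5.6639
P3,-5.358,-4.4959,5.6639
P4,5.358,-4.4959,5.6639
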