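name	position	ganglion	ntype
P001L	0.4728982041558377	G5	inter
P001R	0.261350856100532	G3	motor
P002L	0.3663510147506906	G4	inter
P002R	0.30408021207885666	G4	inter
N005	0.36254010378203355	G4	motor
N006	0.3330825315585031	G4	sensory
N007	0.3328979729914179	G4	inter
N008	0.2970711144987077	G3	inter
P003L	0.726321395570267	G8	sensory
P003R	0.6531572984766126	G7	poly
P004L	0.8251740228922521	G9	poly
P004R	0.7018081948510849	G8	inter
N013	0.5673012027060076	G6	poly
N014	0.7130745479789622	G8	poly
N015	0.6460809040300186	G7	poly
N016	0.6264727532345518	G7	poly
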