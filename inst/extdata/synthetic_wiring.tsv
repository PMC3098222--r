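source	target	type	count
N005	N006	chemical	1
N005	N007	chemical	7
N005	N008	chemical	4
N005	P002L	chemical	3
N005	P002R	chemical	2
N005	P003R	chemical	2
N006	N005	chemical	4
N006	N007	chemical	5
N006	N008	chemical	5
N006	P001L	chemical	4
N006	P001R	chemical	4
N006	P002L	chemical	6
N006	P002R	chemical	6
N006	P003L	chemical	1
N006	P003R	chemical	1
N006	P004L	chemical	1
N007	N005	chemical	2
N007	N006	chemical	2
N007	N008	chemical	4
N007	N013	chemical	1
N007	N014	chemical	1
N007	P001L	chemical	3
N007	P001R	chemical	3
N007	P002L	chemical	5
N007	P002R	chemical	5
N007	P004L	chemical	1
N008	N005	chemical	3
N008	N006	chemical	4
N008	N007	chemical	4
N008	N014	chemical	1
N008	P001L	chemical	4
N008	P001R	chemical	4
N008	P002L	chemical	4
N008	P002R	chemical	4
N008	P004L	chemical	1
N008	P004R	chemical	1
N013	N007	chemical	1
N013	N014	chemical	1
N013	N015	chemical	5
N013	N016	chemical	3
N013	P001R	chemical	1
N013	P002R	chemical	1
N013	P003L	chemical	4
N013	P003R	chemical	4
N013	P004L	chemical	7
N013	P004R	chemical	2
N014	N007	chemical	1
N014	N013	chemical	1
N014	N015	chemical	4
N014	N016	chemical	3
N014	P003L	chemical	5
N014	P003R	chemical	3
N015	N013	chemical	2
N015	N014	chemical	3
N015	N016	chemical	2
N015	P002R	chemical	1
N015	P003L	chemical	7
N015	P003R	chemical	7
N015	P004L	chemical	2
N015	P004R	chemical	2
N016	N007	chemical	1
N016	N008	chemical	1
N016	N013	chemical	4
N016	N014	chemical	1
N016	N015	chemical	3
N016	P001L	chemical	2
N016	P002R	chemical	1
N016	P003L	chemical	5
N016	P003R	chemical	5
N016	P004L	chemical	1
N016	P004R	chemical	2
P001L	N005	chemical	4
P001L	N006	chemical	3
P001L	N007	chemical	4
P001L	N008	chemical	2
P001L	N013	chemical	1
P001L	P001R	chemical	7
P001L	P002L	chemical	2
P001L	P002R	chemical	2
P001L	P003L	chemical	1
P001L	P003R	chemical	1
P001L	P004R	chemical	1
P001R	N005	chemical	4
P001R	N006	chemical	3
P001R	N007	chemical	4
P001R	N008	chemical	2
P001R	N016	chemical	1
P001R	P001L	chemical	5
P001R	P002L	chemical	2
P001R	P002R	chemical	2
P001R	P003L	chemical	1
P001R	P003R	chemical	1
P002L	N005	chemical	5
P002L	N006	chemical	1
P002L	N007	chemical	2
P002L	N015	chemical	1
P002L	P001L	chemical	3
P002L	P001R	chemical	3
P002L	P002R	chemical	4
P002L	P003L	chemical	1
P002L	P003R	chemical	2
P002R	N005	chemical	4
P002R	N006	chemical	1
P002R	N007	chemical	2
P002R	N013	chemical	1
P002R	P001L	chemical	3
P002R	P001R	chemical	3
P002R	P002L	chemical	7
P003L	N006	chemical	1
P003L	N008	chemical	1
P003L	N013	chemical	2
P003L	N014	chemical	1
P003L	N015	chemical	3
P003L	N016	chemical	2
P003L	P002L	chemical	1
P003L	P003R	chemical	7
P003L	P004L	chemical	1
P003L	P004R	chemical	3
P003R	N006	chemical	1
P003R	N013	chemical	2
P003R	N014	chemical	4
P003R	N015	chemical	3
P003R	N016	chemical	2
P003R	P002L	chemical	1
P003R	P003L	chemical	11
P003R	P004L	chemical	2
P003R	P004R	chemical	4
P004L	N007	chemical	1
P004L	N008	chemical	1
P004L	N013	chemical	3
P004L	N014	chemical	2
P004L	N015	chemical	4
P004L	N016	chemical	2
P004L	P003L	chemical	4
P004L	P003R	chemical	1
P004L	P004R	chemical	7
P004R	N005	chemical	1
P004R	N008	chemical	1
P004R	N013	chemical	1
P004R	N014	chemical	2
P004R	N015	chemical	4
P004R	P001L	chemical	2
P004R	P003R	chemical	4
P004R	P004L	chemical	7
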