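microglia	microglia	gene00021	gene00022	gene00023	gene00024	gene00025	gene00026	gene00027	gene00028	gene00029	gene00030	gene00031	gene00032	gene00033	gene00034	gene00035	gene00036	gene00037	gene00038	gene00039	gene00040	gene00041	gene00042	gene00043	gene00044	gene00045
macrophage	macrophage	gene00046	gene00047	gene00048	gene00049	gene00050	gene00051	gene00052	gene00053	gene00054	gene00055	gene00056	gene00057	gene00058	gene00059	gene00060	gene00061	gene00062	gene00063	gene00064	gene00065	gene00066	gene00067	gene00068	gene00069	gene00070
neuron	neuron	gene00071	gene00072	gene00073	gene00074	gene00075	gene00076	gene00077	gene00078	gene00079	gene00080	gene00081	gene00082	gene00083	gene00084	gene00085	gene00086	gene00087	gene00088	gene00089	gene00090	gene00091	gene00092	gene00093	gene00094	gene00095
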