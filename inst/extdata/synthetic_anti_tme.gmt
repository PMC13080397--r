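M1	synthetic placeholder signature	gene0001	gene0002	gene0003	gene0004	gene0005	gene0006	gene0007	gene0008	gene0009	gene0010
Th1	synthetic placeholder signature	gene0011	gene0012	gene0013	gene0014	gene0015	gene0016	gene0017	gene0018	gene0019	gene0020
Anti_tumor_cytokines	synthetic placeholder signature	gene0021	gene0022	gene0023	gene0024	gene0025	gene0026	gene0027	gene0028	gene0029	gene0030
B_cells	synthetic placeholder signature	gene0031	gene0032	gene0033	gene0034	gene0035	gene0036	gene0037	gene0038	gene0039	gene0040
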