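M1_synthetic	M1_synthetic	gene01000	gene01001	gene01002	gene01003	gene01004	gene01005	gene01006	gene01007	gene01008	gene01009	gene01010	gene01011	gene01012	gene01013	gene01014	gene01015	gene01016	gene01017	gene01018	gene01019
M2_synthetic	M2_synthetic	gene01021	gene01022	gene01023	gene01024	gene01025	gene01026	gene01027	gene01028	gene01029	gene01030	gene01031	gene01032	gene01033	gene01034	gene01035	gene01036	gene01037	gene01038	gene01039	gene01040
metabolism_synthetic	metabolism_synthetic	gene01041	gene01042	gene01043	gene01044	gene01045	gene01046	gene01047	gene01048	gene01049	gene01050	gene01051	gene01052	gene01053	gene01054	gene01055	gene01056	gene01057	gene01058	gene01059	gene01060
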