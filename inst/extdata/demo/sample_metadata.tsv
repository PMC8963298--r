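sample_id	batch	run_day
S001	B1	D1
S002	B2	D2
S003	B1	D3
S004	B2	D4
S005	B1	D5
S006	B2	D1
S007	B1	D2
S008	B2	D3
S009	B1	D4
S010	B2	D5
S011	B1	D1
S012	B2	D2
S013	B1	D3
S014	B2	D4
S015	B1	D5
S016	B2	D1
S017	B1	D2
S018	B2	D3
S019	B1	D4
S020	B2	D5
S021	B1	D1
S022	B2	D2
S023	B1	D3
S024	B2	D4
S025	B1	D5
S026	B2	D1
S027	B1	D2
S028	B2	D3
S029	B1	D4
S030	B2	D5
S031	B1	D1
S032	B2	D2
S033	B1	D3
S034	B2	D4
S035	B1	D5
S036	B2	D1
S037	B1	D2
S038	B2	D3
S039	B1	D4
S040	B2	D5
S041	B1	D1
S042	B2	D2
S043	B1	D3
S044	B2	D4
S045	B1	D5
S046	B2	D1
S047	B1	D2
S048	B2	D3
S049	B1	D4
S050	B2	D5
S051	B1	D1
S052	B2	D2
S053	B1	D3
S054	B2	D4
S055	B1	D5
S056	B2	D1
S057	B1	D2
S058	B2	D3
S059	B1	D4
S060	B2	D5
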