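!Series_title	"synthetic miniature series-matrix example (generated fixture, not real data)"
!Series_summary	"six-sample two-group layout for demonstrating read_series_matrix()"
!Sample_geo_accession	"T1"	"T2"	"T3"	"C1"	"C2"	"C3"
!series_matrix_table_begin
"ID_REF"	"T1"	"T2"	"T3"	"C1"	"C2"	"C3"
"probe-00001"	52.1	48.7	55.3	161.0	149.8	157.2
"probe-00002"	210.4	198.9	222.6	205.1	199.7	212.3
"probe-00003"	12.2	11.8	13.1	12.6	12.0	11.4
"probe-00004"	88.5	91.2	84.7	86.9	90.4	89.1
!series_matrix_table_end
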