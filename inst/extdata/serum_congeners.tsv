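congener	family	concentration	detected	detection_limit
2378-TCDD	PCDD	87	TRUE	NA
12378-PeCDD	PCDD	12	TRUE	NA
123478-HxCDD	PCDD	9.0	TRUE	NA
123678-HxCDD	PCDD	33	TRUE	NA
123789-HxCDD	PCDD	8.2	TRUE	NA
1234678-HpCDD	PCDD	35	TRUE	NA
OCDD	PCDD	385	TRUE	NA
2378-TCDF	PCDF	3.2	TRUE	NA
12378-PeCDF	PCDF	2.8	TRUE	NA
23478-PeCDF	PCDF	9.6	TRUE	NA
123478-HxCDF	PCDF	27	TRUE	NA
123678-HxCDF	PCDF	15	TRUE	NA
123789-HxCDF	PCDF	NA	FALSE	3
234678-HxCDF	PCDF	8.4	TRUE	NA
1234678-HpCDF	PCDF	18	TRUE	NA
1234789-HpCDF	PCDF	NA	FALSE	4
OCDF	PCDF	NA	FALSE	13
PCB77	PCB	NA	FALSE	690
PCB81	PCB	NA	FALSE	29
PCB126	PCB	123	TRUE	NA
PCB169	PCB	61	TRUE	NA
PCB105	PCB	5005	TRUE	NA
PCB114	PCB	742	TRUE	NA
PCB118	PCB	22592	TRUE	NA
PCB123	PCB	244	TRUE	NA
PCB156	PCB	5873	TRUE	NA
PCB157	PCB	1579	TRUE	NA
PCB167	PCB	2883	TRUE	NA
PCB189	PCB	938	TRUE	NA
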