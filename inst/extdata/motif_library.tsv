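name	rtk_class	subtype	role	variant	consensus	bold	source
InsR_catalytic	InsR		catalytic	scan	VHRDLAARNC	1,2,3,4,5,6,7,8,9,10	InsR motif table (catalytic loop / FN3 20-mer)
InsR1_FN3	InsR	InsR1	fn3	scan	RYAVYVETDTVADADIGARS	2,3,6,20	InsR motif table (catalytic loop / FN3 20-mer)
InsR2_FN3	InsR	InsR2	fn3	scan	RYAVxVKxxSLxSSxxGAQS	2,3,6,20	InsR motif table (catalytic loop / FN3 20-mer)
InsR3_FN3	InsR	InsR3	fn3	scan	xYAxYVxxYYTDxxKxxSRS	2,3,6,20	InsR motif table (catalytic loop / FN3 20-mer)
FGFR1_catdom	FGFR	FGFR1	kinase_subtype	scan	VAVKMLKEGHTDxELMDLVSEMEMMKMIGTHINIINLLGCCTQDGPLYVVVEYAAHGNLRDYLRNxRxxSGYERxIGQExxxxxxxDLVSFxxQVARGMEYLxSxKCIHRDLAARNVL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,87,88,94,98,100,109,110,111,112,113,115,116,118	FGFR catalytic-domain motif table
FGFR1_catdom_aln	FGFR	FGFR1	kinase_subtype	verbatim	VAVKMLKEGHTDxELMDLVSEMEMMKMIGTHINIINLLGCCTQDGPLYVVVEYAAHGNLRDYLRNxRxxSGYERxIGQExxxxxxxDLVSFxxQVARGMEYLxSxKCIHRDLAARNVL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,87,88,94,98,100,109,110,111,112,113,115,116,118	FGFR catalytic-domain motif table
FGFR2_catdom	FGFR	FGFR2	kinase_subtype	scan	VAVKTxKESAxxRERxDLVQELKVLKxLGxHxNVxSxLxCCxxKxPxFxxLEYMxxGKLQSxLRxSRADTxYxNLHGSSSSxTPxDLxxxxYQxxRGMEFLxRNxxxHRDLAxRNxL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,86,87,93,97,99,108,109,110,111,112,114,115,117	FGFR catalytic-domain motif table
FGFR2_catdom_aln	FGFR	FGFR2	kinase_subtype	verbatim	VAVKTxKESAxxRERxDLVQELKVLKxLGxHxNVxSxLxCCxxKxPxFxxLEYMxxGKLQSxLRxSRADTxYxN-LHGSSSSxTPxDLxxxxYQxxRGMEFLxRNxxxHRDLAxRNxL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,87,88,94,98,100,109,110,111,112,113,115,116,118	FGFR catalytic-domain motif table
FGFR3_catdom	FGFR	FGFR3	kinase_subtype	scan	VAVKGVKxGAGxKEKQDLLxELxIMQHxGxxxNVVTLLGCCTQQEPxxVIMEYVMFGKLLxFLRDHRTRxNYYNFSSDTxALTSxDLTRFACQVAxGCEYxQSRGIIHRDLAxRNxL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,86,87,93,97,99,108,109,110,111,112,114,115,117	FGFR catalytic-domain motif table
FGFR3_catdom_aln	FGFR	FGFR3	kinase_subtype	verbatim	VAVKGVKxGAGxKEKQDLLxELxIMQHxGxxxNVVTLLGCCTQQEPxxVIMEYVMFGKLLxFLRDHRTRxNYYN-FSSDTxALTSxDLTRFACQVAxGCEYxQSRGIIHRDLAxRNxL	1,2,3,4,7,14,17,18,21,29,33,38,40,41,46,52,53,57,59,63,64,67,72,87,88,94,98,100,109,110,111,112,113,115,116,118	FGFR catalytic-domain motif table
PVR1_catdom	PVR	PVR1	kinase_subtype	scan	YQIAKGMEYLAFKKVLHGDLAARNVLLxxNNVVKISDFGLAKDIYxNxNYKKxxxGPVPVKW	2,4,6,7,9,10,16,17,18,19,20,21,22,23,24,26,27,31,34,35,36,37,38,39,45,50,52,59,61,62	PVR catalytic-domain motif table
PVR2A_catdom	PVR	PVR2A	kinase_subtype	scan	WQxAxGMxYLSRRxxLHGDLAARNLLLxDNNVxKISDFGxSRxxYxxxxYxKxxDxxxPxKW	2,4,6,7,9,10,16,17,18,19,20,21,22,23,24,26,27,31,34,35,36,37,38,39,45,50,52,59,61,62	PVR catalytic-domain motif table
PVR2B_catdom	PVR	PVR2B	kinase_subtype	scan	WQVAxGMxYLxxRKVLHGDLAARNLLLxDDNxxKISDFGLSRxMYKKDxYMKKxDDLMPIKW	2,4,6,7,9,10,16,17,18,19,20,21,22,23,24,26,27,31,34,35,36,37,38,39,45,50,52,59,61,62	PVR catalytic-domain motif table
EGFR1_context	EGFR	EGFR1	egfr_context	scan	SPNQALLRIVKEHNEGMQYLEEKNFIHRDLATRNVLLDSELNVKIGDFG	27,28,29,30,31,33,34,47,48,49	artifact-derived (synthetic); not a published motif
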