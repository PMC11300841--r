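canonical_name	accession	type
hsa-miR-501-3p	MIMAT0004774	mature
hsa-miR-502-3p	MIMAT0004775	mature
hsa-miR-877-5p	MIMAT0004949	mature
hsa-miR-133b	MIMAT0000770	mature
hsa-miR-221-3p	MIMAT0000278	mature
hsa-let-7b-5p	MIMAT0000063	mature
hsa-let-7b-3p	MIMAT0004482	mature
hsa-miR-21-5p	MIMAT0000076	mature
hsa-miR-9001-5p	MIMAT990015	mature
hsa-miR-9002-3p	MIMAT990023	mature
hsa-miR-9003-5p	MIMAT990035	mature
hsa-miR-9004-3p	MIMAT990043	mature
hsa-miR-9005-5p	MIMAT990055	mature
hsa-miR-9006-3p	MIMAT990063	mature
hsa-miR-9007-5p	MIMAT990075	mature
hsa-miR-9008-3p	MIMAT990083	mature
hsa-miR-9009-5p	MIMAT990095	mature
hsa-miR-9010-3p	MIMAT990103	mature
hsa-miR-9011-5p	MIMAT990115	mature
hsa-miR-9012-3p	MIMAT990123	mature
hsa-miR-9013-5p	MIMAT990135	mature
hsa-miR-9014-3p	MIMAT990143	mature
hsa-miR-9015-5p	MIMAT990155	mature
hsa-miR-9016-3p	MIMAT990163	mature
hsa-miR-9017-5p	MIMAT990175	mature
hsa-miR-9018-3p	MIMAT990183	mature
hsa-miR-9019-5p	MIMAT990195	mature
hsa-miR-9020-3p	MIMAT990203	mature
hsa-miR-9021-5p	MIMAT990215	mature
hsa-miR-9022-3p	MIMAT990223	mature
hsa-miR-9023-5p	MIMAT990235	mature
hsa-miR-9024-3p	MIMAT990243	mature
hsa-miR-9025-5p	MIMAT990255	mature
hsa-mir-21	MI0000077	precursor
hsa-let-7b	MI0000063	precursor
hsa-mir-9001	MI900010	precursor
hsa-mir-9002	MI900020	precursor
hsa-mir-9003	MI900030	precursor
hsa-mir-9004	MI900040	precursor
hsa-mir-9005	MI900050	precursor
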