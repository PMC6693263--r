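name	best_hit_desc	signal_band	c_pattern	conserved_band	published_category
Cluster_1	Lamda-potassium channel toxin (ADT64271.1)	some	TRUE	high	new_toxins_in_existing_family
Cluster_2	Hypothetical secreted protein (ADY39531.1)	high	TRUE	high	novel_putative_toxin_family
Cluster_3	U6-buthitoxin-Hj1a (ADY39519.1)	high	TRUE	high	new_toxins_in_existing_family
Cluster_4	Orphan peptide AbOp-11 (AIX87714.1)	high	FALSE	high	novel_putative_secreted_protein
Cluster_5	Hypothetical secreted protein (ADY39514.1)	high	TRUE	high	novel_putative_toxin_family
Cluster_6	venom peptide HtC4Tx1 (AOF40173.1)	low	TRUE	low	novel_putative_toxin_family
Cluster_7	hypothetical protein (WP_063562212.1)	low	TRUE	low	novel_putative_toxin_family
Cluster_8	Orphan peptide AbOp-18 (AIX87708.1)	high	FALSE	high	new_toxins_in_existing_family
Cluster_9	Venom toxin meuTx23 (AMX81480.1)	low	FALSE	high	new_toxins_in_existing_family
Cluster_10	Hypothetical secreted protein (ADY39511.1)	high	FALSE	low	novel_putative_secreted_protein
Cluster_11	RNA-binding protein, putative (SCO66159.1)	low	FALSE	some	novel_putative_secreted_protein
Cluster_12	Uncharacterized protein (XP_023221782.1)	high	TRUE	high	novel_putative_toxin_family
Cluster_13	Potassium channel toxin alpha-KTx 4.5 (Q5G8B6.1)	low	TRUE	high	new_toxins_in_existing_family
Cluster_14	Hypothetical protein (AEX09189.1)	high	FALSE	some	novel_putative_secreted_protein
Cluster_15	Hypothetical protein (GAU10035.1)	low	TRUE	some	novel_putative_toxin_family
Singlet_1	No Hit	low	FALSE	low	novel_putative_secreted_protein
Singlet_2	No Hit	low	FALSE	low	novel_putative_secreted_protein
Singlet_3	Hypothetical protein (AEX09189.1)	high	FALSE	some	novel_putative_secreted_protein
Singlet_4	Orphan peptide AbOp-11 (AIX87714.1)	high	FALSE	low	novel_putative_secreted_protein
Singlet_5	Potassium channel toxin kappa-KTx (P0DJ41.1)	some	TRUE	low	new_toxins_in_existing_family
Singlet_6	Venom peptide Htgkr2 (AOF40260.1)	some	FALSE	low	novel_putative_secreted_protein
Singlet_7	No Hit	low	TRUE	low	novel_putative_toxin
Singlet_8	SH3 domain and tetratricopeptide repeat-containing protein (XP_004574858.2)	low	FALSE	low	novel_putative_secreted_protein
Singlet_9	Putative antimicrobial peptide (AEX09192.1)	high	FALSE	high	novel_putative_amp
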