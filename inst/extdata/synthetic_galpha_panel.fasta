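>AtGPA1_synthetic
MGLLCSRSRHHTNAQNTDQQESVAEEPCITMNIRNAVKCQPYVLLLLGAGESGKSTIFKQTAKTLIFRDCAMPAETCIDR
PESKIFLSKRYWSKQEKVCYRKGQQTWLDGWGTVWPYVCTPPYPIEGINCIESAKFWTFALENHEFARSEMYEKDIHWEP
GIDVEVGNSVNDHNQGVSFVAEYQPEAELRVKTTGIVETQFCMYYEFGKIYDMHYLQDVGGQRGVNWGIACFYGSDDQKD
RSRYKIESAEDYLAFKYPQRKMTAWKNSFRIMYYMEHSENFFTCEMYFLNKKDCFICANSSVHEHGDSSISPEMHCAQIM
LEFNTCATDTITRDMEPGQVENVCMREYDVCVNFPPAFGQSQNKWQFRQCHDFYHFIPGV
>OsRGA1_synthetic
MGLLCSRSRHHTGNAQNTDQQESVAVEPCITMNIRNAVKCQPYVLLLLGAGESGKSTIFKQTAKTLIFRDCAMPAETCID
RPESKIFLSKFYWSKQEKVCYRKGQQTWLDGWGTVWPYVCTPPYPIEGINCIESAKFWTFALENHEFARSAMYEKDIHWE
PGIDVEVGNSVNDHNQGVSFVAEYQPEAELRVKTNGIVETQFCMYYEFGKIYDMHYLQDVGGQRGVNWGIACFYGSDDQK
DRSRYKIESAMDYLAFKYPQRKMTAWKNSFRIMYYMEHSENFFTCEMYFLNKKDCFICANSSVHEHGDSSESPEMHCAQI
MLEFNTCATDTITRDMEPGQVENVCMREYDVCVNFPPAFGWSQNKWQFRQCHDFYHFIPGV
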