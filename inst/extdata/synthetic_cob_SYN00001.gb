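LOCUS       SYN00001             291 bp    DNA     linear   SYN 01-JAN-2020
DEFINITION  Synthetica exemplaris mitochondrial cytochrome b (cob) gene,
            synthetic record emitted by the cobintron generator for parser tests.
ACCESSION   SYN00001
SOURCE      Synthetica exemplaris
  ORGANISM  Synthetica exemplaris
            Eukaryota; Fungi; Synthetomycota.
FEATURES             Location/Qualifiers
     source          1..291
                     /organism="Synthetica exemplaris"
     CDS             join(1..27,73..95,156..291)
                     /gene="cob"
                     /product="cytochrome b"
                     /transl_table=4
ORIGIN
        1 atggatgcga aacgcggacc ggactgtcgg tgcgccttgt tcgtgctgtt cggctcgatg
       61 ccgctctgtt aggataatag ctcaccgcgc gcgttctaga ataactagag cttatcgtcc
      121 ctgtcgatcg aattcgtttc ctaccatctg aatcggaccg gctataatga agggcgctgc
      181 ccggcgttcg tgccaaccga gatccgggaa tgtcagtgga gcgtcatgtt agcctgtaga
      241 ccgacagccg acgtgatccc aacagagcgt tatacgagct ccgatgctta a
//
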