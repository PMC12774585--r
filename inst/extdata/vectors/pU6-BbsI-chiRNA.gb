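LOCUS       pU6-BbsI-chiRNA   1253 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pU6-BbsI-chiRNA.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in guide RNA vector
FEATURES             Location/Qualifiers
     source          1..1253
                     /label="pU6-BbsI-chiRNA"
                     /note="kind=guide; synthetic stand-in"
     misc_feature    1..700
                     /label="backbone"
                     /note="synthetic stand-in backbone"
     promoter        701..950
                     /label="U6 promoter"
                     /note="synthetic stand-in"
     misc_feature    951..954
                     /label="BbsI overhang (left)"
     misc_feature    955..962
                     /label="BbsI"
                     /note="recognition, bottom strand"
     misc_feature    963..982
                     /label="stuffer"
                     /note="released by BbsI digestion"
     misc_feature    983..990
                     /label="BbsI"
                     /note="recognition, top strand"
     misc_feature    991..1066
                     /label="gRNA scaffold"
     terminator      1067..1073
                     /label="U6 terminator"
     misc_feature    1074..1253
                     /label="backbone"
                     /note="synthetic stand-in backbone"
ORIGIN
        1 ttctaaacta acggtgtcgc gcgagccatg cgaccgcttg ccaggtgctt ctgtgatatg
       61 taaactagct caaatggtgg tgtgatatga agtcaagctt gagtcttaga gcaaggaagt
      121 gtcttaacag tgctctgaga cgcgtgtgtg attacatcat actagcgcgg gttgtaaatg
      181 ttgaccggcc ctcagaggag tagggctccc aggacagctc agcggcaatg gggacgctcc
      241 tggaactcac agctcgtcga ataacagtag caatactttc atcgagttgt gcagtgagag
      301 ggatgttagg aatgggttgt gattatctcg atttcggccg ccgagtgcca gggccaatac
      361 taaaaccgga ttaggaaagt taggtcaatg ccattgtttc cttggttgtg cgaccacctt
      421 ggatacaccc tcagacccgt ctcttgtcgc caaattcgac ctatacgagc gtctgggctg
      481 tagcgcctta gacgaagata acaagagaga cagtacagtc gggcaggtat aaaaagtgag
      541 ccgctcctaa ggggcctagg ctaatattct gtttagggta caattgtgac tgattgatac
      601 aggtcatcgg tccatcggct gcttaatggc taaagagcct cagccgagtg ctcttcaaaa
      661 taatggtcgc aatagaagga atagtgaaag ttatccctgg ctaataacga ggtagattga
      721 ccacctcctc gcaatgtcaa caacatttgc aagccttacg aagcggtggt cctagaacca
      781 tgccttgcgc agttttgcgc atgaggttcc agccttacga gccggcctgg tcttgcgacg
      841 gttcagctgg gtgacaagct aggagtattt ccgggcagtc aactagcagc gcactttgat
      901 cccctgtaat tattgaaact cgtccaaaaa atatagtaaa tttggggctt cttcaagtct
      961 tctctcaata ggcggcgggt atgaagacaa gttttagagc tagaaatagc aagttaaaat
     1021 aaggctagtc cgttatcaac ttgaaaaagt ggcaccgagt cggtgctttt tttccttttg
     1081 gacgcgaaaa acacgtggcg acgggccgcc cgatcgcagc ccgggggggg acgaaaacct
     1141 ggagcggtct gtggcgagcg tctcttcttc ttggactgga actacaaggg ctaacgatcc
     1201 ccaccacagg gacaggtcgc caagtttagg cggccacttc catcgatcta ctc
//
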