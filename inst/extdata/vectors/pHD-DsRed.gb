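LOCUS       pHD-DsRed         2107 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pHD-DsRed.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in deletion vector
FEATURES             Location/Qualifiers
     source          1..2107
                     /label="pHD-DsRed"
                     /note="kind=deletion; synthetic stand-in"
     misc_feature    1..700
                     /label="backbone"
                     /note="synthetic stand-in backbone"
     misc_feature    701..706
                     /label="EcoRI site"
     misc_feature    707..714
                     /label="NotI site"
     misc_feature    714..714
                     /label="HA_left_slot"
                     /note="slot_at=714"
     misc_feature    715..748
                     /label="loxP"
     promoter        749..1048
                     /label="3xP3 promoter"
                     /note="synthetic stand-in"
     CDS             1049..1729
                     /label="DsRed"
                     /note="synthetic stand-in ORF"
     terminator      1730..1879
                     /label="terminator"
                     /note="synthetic stand-in"
     misc_feature    1880..1913
                     /label="loxP"
     misc_feature    1913..1913
                     /label="HA_right_slot"
                     /note="slot_at=1913"
     misc_feature    1914..1921
                     /label="AscI site"
     misc_feature    1922..1927
                     /label="XhoI site"
     misc_feature    1928..2107
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
      661 taatggtcgc aatagaagga atagtgaaag ttatccctgg gaattcgcgg ccgcataact
      721 tcgtataatg tatgctatac gaagttataa gactagctct ctgtaatgcc cgaccaacag
      781 tgggaggaca tcatgaaggt aacgacgcca tcctggagcc acacgccgcc gaacactaac
      841 acactcatag cggttcggca agtggtaata tccctcgacc gaaggcttac cttgcagccc
      901 tagcccagtg agattttatg ccgaagtatc gtacaggcct accagtgaaa gttgtctcta
      961 agctggagag aaaggtctta acttcattct catgctcagg ctgtgatttt tttacgctga
     1021 ctaggctaac cccacaaaac aagggcaaat gatcatcggg cttagttggg catggctcga
     1081 aacagacaca agttcgtgta ggactaacat catcttattg cttggcgttc agcgaaacaa
     1141 actgtggcat cggcctaagg gaacccaact gacggaaaga gtatcgccta gacaccggca
     1201 acatgaatgt caagccactc tgcgatcaga tgatcgaata agatctaggt gcctccatag
     1261 tgataaatgg gtgtcacgcg aactttcatc acactgcaga gcaggtgtac catcgtgccg
     1321 ttctggcggc ataagattcg gcaagtgtac caaatgcggc tactcgacac gtaaactgtc
     1381 cagtccattt ggcggaaggg gtctcagtgg cgcgagcgct ctttcccgtt ccatgaaaag
     1441 ctcccctttt acagttcgat acatttatat aaggcgccac gtccgccaca gaaatgtgtc
     1501 tgacaggtat caaacgatgg cagttcaagg tagagcgaat cactctgcca accatccatg
     1561 tgtgcttcca gctcgatcgt gccagaaggc cgaccctggt caatgcctac tttctcgcga
     1621 gcgcactctt cccgactcgg tacattgggt aaatctggct ggtccggagg gagaaatacc
     1681 atctgtgatt gccgtaacgg agaatctgtc ccttaggaac ctgttataac catttaccaa
     1741 gatcctcttt tccgacaggg acgcagttta ccaactcaca agtttcaaag tcttaggcac
     1801 cgcgaagagg tagagttttt acatcacgcg acgaagaaaa acggaatgat cagaataccc
     1861 gcagagacct gattacgcta taacttcgta taatgtatgc tatacgaagt tatggcgcgc
     1921 cctcgagcct tttggacgcg aaaaacacgt ggcgacgggc cgcccgatcg cagcccgggg
     1981 ggggacgaaa acctggagcg gtctgtggcg agcgtctctt cttcttggac tggaactaca
     2041 agggctaacg atccccacca cagggacagg tcgccaagtt taggcggcca cttccatcga
     2101 tctactc
//
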