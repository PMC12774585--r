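LOCUS       pHD-SspB-ExLK-EGFP-DsRed 3233 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pHD-SspB-ExLK-EGFP-DsRed.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in N-terminal tagging vector (EGFP)
FEATURES             Location/Qualifiers
     source          1..3233
                     /label="pHD-SspB-ExLK-EGFP-DsRed"
                     /note="kind=tagN; frame_offset=0; synthetic stand-in
                     fusion cassette"
     misc_feature    1..700
                     /label="backbone"
                     /note="synthetic stand-in backbone"
     misc_feature    701..706
                     /label="EcoRI site"
     misc_feature    707..714
                     /label="NotI site"
     misc_feature    715..720
                     /label="NdeI site"
     misc_feature    720..720
                     /label="HA_left_slot"
                     /note="slot_at=720"
     CDS             721..1059
                     /label="SspB(R73Q)"
                     /note="synthetic stand-in ORF"
     misc_feature    1060..1110
                     /label="ExLK linker"
                     /note="extended flexible linker; in-frame MluI"
     CDS             1111..1830
                     /label="EGFP"
                     /note="synthetic stand-in ORF"
     misc_feature    1831..1864
                     /label="loxP"
     promoter        1865..2164
                     /label="3xP3 promoter"
                     /note="synthetic stand-in"
     CDS             2165..2845
                     /label="DsRed"
                     /note="synthetic stand-in ORF"
     terminator      2846..2995
                     /label="terminator"
                     /note="synthetic stand-in"
     misc_feature    2996..3029
                     /label="loxP"
     misc_feature    3030..3031
                     /label="frame spacer"
                     /note="keeps residual insert in frame after floxing"
     misc_feature    3031..3031
                     /label="HA_right_slot"
                     /note="slot_at=3031"
     misc_feature    3032..3039
                     /label="AscI site"
     misc_feature    3040..3045
                     /label="XhoI site"
     misc_feature    3046..3053
                     /label="PmeI site"
     misc_feature    3054..3233
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
      661 taatggtcgc aatagaagga atagtgaaag ttatccctgg gaattcgcgg ccgccatatg
      721 cggaaagcta tgcgctttct actatcgcgt acattttccc ttgatcactg cacccacgat
      781 ggggaaatag gaatttctcg gccgaaaacc tcctatgtat cccatcttca atttgtaaaa
      841 gatgccaagt tctgcgcgtt agaacaagta ggaaagcctt gcagatttgg agcaaggcgt
      901 tcgaaacact cttactgtag actgttaggt acgtgctgcc gccaaagacg acgagcgact
      961 cgcgtaggac gtcgattgca tgaatcatgg acccaccaaa ccaggcgaag cgactccggg
     1021 cgatatgaca acgcgatgcc atacaaacag ggggaattca cgcgtatagg tttaggagct
     1081 gggacctgcc acggcgaatt gatgctaccg ttagatgccc ggccagagat ggatcgaatc
     1141 catgtagacg gaaaactatt gacgcagaaa attgccagag ccatgcatag gaggagagat
     1201 ggtagccaca aggctcatgc tgcacaatca tccatagcgc gaagcaaaag caaatattac
     1261 aacggaggca gttctattat acacgcaagc ggggttgaag ataagcggaa acctaagcgg
     1321 ttgttagaat gcgtccgggc aacatatact gtcccgccaa gacggatata catgtccatc
     1381 aagacatcgg cccacgctgg actgagcttc attatcctcc aagatctgta tccgcgacgg
     1441 tgtaaagagg gaacgtttac ggactttcct cgcggttacg ataccaggtc gggcttaacc
     1501 gatccagatc gcttaggagc ccctgcatgc gaaaataatc atttgcatgt tcttagagtt
     1561 acccccagtt actgtcccat atgttacgac atcaataggg agacagtgca ctcatcaatg
     1621 acggaaaaac gcaccaacag gaacgaacta ccacacttcc tacttcagca gtgtatccga
     1681 ctatatctgc tacctctggg acagttttcg ataattacac gtaccgatgc aactaggatg
     1741 ctaccgggcc gccgcaacaa tccatcggag cgtagggctc atctgcctaa ctcttctcat
     1801 catcggatgg tatatcagaa gactcaaaca ataacttcgt ataatgtatg ctatacgaag
     1861 ttataagact agctctctgt aatgcccgac caacagtggg aggacatcat gaaggtaacg
     1921 acgccatcct ggagccacac gccgccgaac actaacacac tcatagcggt tcggcaagtg
     1981 gtaatatccc tcgaccgaag gcttaccttg cagccctagc ccagtgagat tttatgccga
     2041 agtatcgtac aggcctacca gtgaaagttg tctctaagct ggagagaaag gtcttaactt
     2101 cattctcatg ctcaggctgt gattttttta cgctgactag gctaacccca caaaacaagg
     2161 gcaaatgatc atcgggctta gttgggcatg gctcgaaaca gacacaagtt cgtgtaggac
     2221 taacatcatc ttattgcttg gcgttcagcg aaacaaactg tggcatcggc ctaagggaac
     2281 ccaactgacg gaaagagtat cgcctagaca ccggcaacat gaatgtcaag ccactctgcg
     2341 atcagatgat cgaataagat ctaggtgcct ccatagtgat aaatgggtgt cacgcgaact
     2401 ttcatcacac tgcagagcag gtgtaccatc gtgccgttct ggcggcataa gattcggcaa
     2461 gtgtaccaaa tgcggctact cgacacgtaa actgtccagt ccatttggcg gaaggggtct
     2521 cagtggcgcg agcgctcttt cccgttccat gaaaagctcc ccttttacag ttcgatacat
     2581 ttatataagg cgccacgtcc gccacagaaa tgtgtctgac aggtatcaaa cgatggcagt
     2641 tcaaggtaga gcgaatcact ctgccaacca tccatgtgtg cttccagctc gatcgtgcca
     2701 gaaggccgac cctggtcaat gcctactttc tcgcgagcgc actcttcccg actcggtaca
     2761 ttgggtaaat ctggctggtc cggagggaga aataccatct gtgattgccg taacggagaa
     2821 tctgtccctt aggaacctgt tataaccatt taccaagatc ctcttttccg acagggacgc
     2881 agtttaccaa ctcacaagtt tcaaagtctt aggcaccgcg aagaggtaga gtttttacat
     2941 cacgcgacga agaaaaacgg aatgatcaga atacccgcag agacctgatt acgctataac
     3001 ttcgtataat gtatgctata cgaagttatc cggcgcgccc tcgaggttta aacccttttg
     3061 gacgcgaaaa acacgtggcg acgggccgcc cgatcgcagc ccgggggggg acgaaaacct
     3121 ggagcggtct gtggcgagcg tctcttcttc ttggactgga actacaaggg ctaacgatcc
     3181 ccaccacagg gacaggtcgc caagtttagg cggccacttc catcgatcta ctc
//
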