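LOCUS       pHD-mCherry-ExLK-SspB-DsRed 3224 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pHD-mCherry-ExLK-SspB-DsRed.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in C-terminal tagging vector (mCherry)
FEATURES             Location/Qualifiers
     source          1..3224
                     /label="pHD-mCherry-ExLK-SspB-DsRed"
                     /note="kind=tagC; frame_offset=0; synthetic stand-in
                     fusion cassette"
     misc_feature    1..700
                     /label="backbone"
                     /note="synthetic stand-in backbone"
     misc_feature    701..708
                     /label="SrfI site"
     misc_feature    709..714
                     /label="EcoRI site"
     misc_feature    715..722
                     /label="NotI site"
     misc_feature    722..722
                     /label="HA_left_slot"
                     /note="slot_at=722"
     misc_feature    723..756
                     /label="loxP"
     promoter        757..1056
                     /label="3xP3 promoter"
                     /note="synthetic stand-in"
     CDS             1057..1737
                     /label="DsRed"
                     /note="synthetic stand-in ORF"
     terminator      1738..1887
                     /label="terminator"
                     /note="synthetic stand-in"
     misc_feature    1888..1921
                     /label="loxP"
     misc_feature    1922..1923
                     /label="frame spacer"
                     /note="keeps residual insert in frame after floxing"
     CDS             1924..2634
                     /label="mCherry"
                     /note="synthetic stand-in ORF"
     misc_feature    2635..2685
                     /label="ExLK linker"
                     /note="extended flexible linker; in-frame MluI"
     CDS             2686..3024
                     /label="SspB(R73Q)"
                     /note="synthetic stand-in ORF"
     misc_feature    3024..3024
                     /label="HA_right_slot"
                     /note="slot_at=3024"
     misc_feature    3025..3030
                     /label="BglII site"
     misc_feature    3031..3036
                     /label="XhoI site"
     misc_feature    3037..3044
                     /label="PmeI site"
     misc_feature    3045..3224
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
      661 taatggtcgc aatagaagga atagtgaaag ttatccctgg gcccgggcga attcgcggcc
      721 gcataacttc gtataatgta tgctatacga agttataaga ctagctctct gtaatgcccg
      781 accaacagtg ggaggacatc atgaaggtaa cgacgccatc ctggagccac acgccgccga
      841 acactaacac actcatagcg gttcggcaag tggtaatatc cctcgaccga aggcttacct
      901 tgcagcccta gcccagtgag attttatgcc gaagtatcgt acaggcctac cagtgaaagt
      961 tgtctctaag ctggagagaa aggtcttaac ttcattctca tgctcaggct gtgatttttt
     1021 tacgctgact aggctaaccc cacaaaacaa gggcaaatga tcatcgggct tagttgggca
     1081 tggctcgaaa cagacacaag ttcgtgtagg actaacatca tcttattgct tggcgttcag
     1141 cgaaacaaac tgtggcatcg gcctaaggga acccaactga cggaaagagt atcgcctaga
     1201 caccggcaac atgaatgtca agccactctg cgatcagatg atcgaataag atctaggtgc
     1261 ctccatagtg ataaatgggt gtcacgcgaa ctttcatcac actgcagagc aggtgtacca
     1321 tcgtgccgtt ctggcggcat aagattcggc aagtgtacca aatgcggcta ctcgacacgt
     1381 aaactgtcca gtccatttgg cggaaggggt ctcagtggcg cgagcgctct ttcccgttcc
     1441 atgaaaagct ccccttttac agttcgatac atttatataa ggcgccacgt ccgccacaga
     1501 aatgtgtctg acaggtatca aacgatggca gttcaaggta gagcgaatca ctctgccaac
     1561 catccatgtg tgcttccagc tcgatcgtgc cagaaggccg accctggtca atgcctactt
     1621 tctcgcgagc gcactcttcc cgactcggta cattgggtaa atctggctgg tccggaggga
     1681 gaaataccat ctgtgattgc cgtaacggag aatctgtccc ttaggaacct gttataacca
     1741 tttaccaaga tcctcttttc cgacagggac gcagtttacc aactcacaag tttcaaagtc
     1801 ttaggcaccg cgaagaggta gagtttttac atcacgcgac gaagaaaaac ggaatgatca
     1861 gaatacccgc agagacctga ttacgctata acttcgtata atgtatgcta tacgaagtta
     1921 tccgcgagcc acactgtgct agcaggttac catcgagaca gaaaatctcc acgtttctgg
     1981 gtcgccccgt ttttattgaa tatgggggtc ggggcgggca ccagcaacgg ccttttgctt
     2041 ttcgacgcgt cgtcgcttca ccagcccccc caccttgatt tagatggaga tcaagagcgt
     2101 gtgagcttgc tcaataggag cacccgcacc ctactcacta actctagaat ccgactcctc
     2161 atctacacta agtcctgggc atccgatgcg aatgcctttc cgacgtcata taggataccg
     2221 acacatagag gactcttcat ctgtccgggg aggattacat gcacaagtag ttccagcctg
     2281 ttccttccca ggttgggacc ggtcaagccg gtcctggggc ctgcgcggtg tgggaacaat
     2341 atacttacac ccactaacgt gccaagcgct gttagagtcc tcagggtagg tcaaagcatt
     2401 atcctaataa aggattacgc tggttcgccg ggacacgggg agcggacagt gccagatacg
     2461 gccctcgcat ctccgaacct ggtcgctact ccttgttcac tgtacgcgat gcatctcgac
     2521 ttagcgcctc gaaattcaca cgtagtctct aaacctttct gtctaagttc cacatccgca
     2581 tgccagcgag tgtcgcctat acccggacgg cggccggata acaacaccct taacacgcgt
     2641 ataggtttag gagctgggac ctgccacggc gaattgatgc taccgcggaa agctatgcgc
     2701 tttctactat cgcgtacatt ttcccttgat cactgcaccc acgatgggga aataggaatt
     2761 tctcggccga aaacctccta tgtatcccat cttcaatttg taaaagatgc caagttctgc
     2821 gcgttagaac aagtaggaaa gccttgcaga tttggagcaa ggcgttcgaa acactcttac
     2881 tgtagactgt taggtacgtg ctgccgccaa agacgacgag cgactcgcgt aggacgtcga
     2941 ttgcatgaat catggaccca ccaaaccagg cgaagcgact ccgggcgata tgacaacgcg
     3001 atgccataca aacaggggga attcagatct ctcgaggttt aaaccctttt ggacgcgaaa
     3061 aacacgtggc gacgggccgc ccgatcgcag cccggggggg gacgaaaacc tggagcggtc
     3121 tgtggcgagc gtctcttctt cttggactgg aactacaagg gctaacgatc cccaccacag
     3181 ggacaggtcg ccaagtttag gcggccactt ccatcgatct actc
//
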