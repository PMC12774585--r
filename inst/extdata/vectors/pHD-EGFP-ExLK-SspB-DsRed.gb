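LOCUS       pHD-EGFP-ExLK-SspB-DsRed 3233 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pHD-EGFP-ExLK-SspB-DsRed.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in C-terminal tagging vector (EGFP)
FEATURES             Location/Qualifiers
     source          1..3233
                     /label="pHD-EGFP-ExLK-SspB-DsRed"
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
     CDS             1924..2643
                     /label="EGFP"
                     /note="synthetic stand-in ORF"
     misc_feature    2644..2694
                     /label="ExLK linker"
                     /note="extended flexible linker; in-frame MluI"
     CDS             2695..3033
                     /label="SspB(R73Q)"
                     /note="synthetic stand-in ORF"
     misc_feature    3033..3033
                     /label="HA_right_slot"
                     /note="slot_at=3033"
     misc_feature    3034..3039
                     /label="BglII site"
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
     1921 tccttagatg cccggccaga gatggatcga atccatgtag acggaaaact attgacgcag
     1981 aaaattgcca gagccatgca taggaggaga gatggtagcc acaaggctca tgctgcacaa
     2041 tcatccatag cgcgaagcaa aagcaaatat tacaacggag gcagttctat tatacacgca
     2101 agcggggttg aagataagcg gaaacctaag cggttgttag aatgcgtccg ggcaacatat
     2161 actgtcccgc caagacggat atacatgtcc atcaagacat cggcccacgc tggactgagc
     2221 ttcattatcc tccaagatct gtatccgcga cggtgtaaag agggaacgtt tacggacttt
     2281 cctcgcggtt acgataccag gtcgggctta accgatccag atcgcttagg agcccctgca
     2341 tgcgaaaata atcatttgca tgttcttaga gttaccccca gttactgtcc catatgttac
     2401 gacatcaata gggagacagt gcactcatca atgacggaaa aacgcaccaa caggaacgaa
     2461 ctaccacact tcctacttca gcagtgtatc cgactatatc tgctacctct gggacagttt
     2521 tcgataatta cacgtaccga tgcaactagg atgctaccgg gccgccgcaa caatccatcg
     2581 gagcgtaggg ctcatctgcc taactcttct catcatcgga tggtatatca gaagactcaa
     2641 acaacgcgta taggtttagg agctgggacc tgccacggcg aattgatgct accgcggaaa
     2701 gctatgcgct ttctactatc gcgtacattt tcccttgatc actgcaccca cgatggggaa
     2761 ataggaattt ctcggccgaa aacctcctat gtatcccatc ttcaatttgt aaaagatgcc
     2821 aagttctgcg cgttagaaca agtaggaaag ccttgcagat ttggagcaag gcgttcgaaa
     2881 cactcttact gtagactgtt aggtacgtgc tgccgccaaa gacgacgagc gactcgcgta
     2941 ggacgtcgat tgcatgaatc atggacccac caaaccaggc gaagcgactc cgggcgatat
     3001 gacaacgcga tgccatacaa acagggggaa ttcagatctc tcgaggttta aacccttttg
     3061 gacgcgaaaa acacgtggcg acgggccgcc cgatcgcagc ccgggggggg acgaaaacct
     3121 ggagcggtct gtggcgagcg tctcttcttc ttggactgga actacaaggg ctaacgatcc
     3181 ccaccacagg gacaggtcgc caagtttagg cggccacttc catcgatcta ctc
//
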