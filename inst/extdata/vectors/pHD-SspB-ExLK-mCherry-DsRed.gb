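LOCUS       pHD-SspB-ExLK-mCherry-DsRed 3224 bp    DNA     circular SYN 01-JAN-2026
DEFINITION  pHD-SspB-ExLK-mCherry-DsRed.
ACCESSION   .
VERSION     .
KEYWORDS    .
SOURCE      synthetic DNA construct
  ORGANISM  synthetic DNA construct
COMMENT     synthetic stand-in N-terminal tagging vector (mCherry)
FEATURES             Location/Qualifiers
     source          1..3224
                     /label="pHD-SspB-ExLK-mCherry-DsRed"
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
     CDS             1111..1821
                     /label="mCherry"
                     /note="synthetic stand-in ORF"
     misc_feature    1822..1855
                     /label="loxP"
     promoter        1856..2155
                     /label="3xP3 promoter"
                     /note="synthetic stand-in"
     CDS             2156..2836
                     /label="DsRed"
                     /note="synthetic stand-in ORF"
     terminator      2837..2986
                     /label="terminator"
                     /note="synthetic stand-in"
     misc_feature    2987..3020
                     /label="loxP"
     misc_feature    3021..3022
                     /label="frame spacer"
                     /note="keeps residual insert in frame after floxing"
     misc_feature    3022..3022
                     /label="HA_right_slot"
                     /note="slot_at=3022"
     misc_feature    3023..3030
                     /label="AscI site"
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
      661 taatggtcgc aatagaagga atagtgaaag ttatccctgg gaattcgcgg ccgccatatg
      721 cggaaagcta tgcgctttct actatcgcgt acattttccc ttgatcactg cacccacgat
      781 ggggaaatag gaatttctcg gccgaaaacc tcctatgtat cccatcttca atttgtaaaa
      841 gatgccaagt tctgcgcgtt agaacaagta ggaaagcctt gcagatttgg agcaaggcgt
      901 tcgaaacact cttactgtag actgttaggt acgtgctgcc gccaaagacg acgagcgact
      961 cgcgtaggac gtcgattgca tgaatcatgg acccaccaaa ccaggcgaag cgactccggg
     1021 cgatatgaca acgcgatgcc atacaaacag ggggaattca cgcgtatagg tttaggagct
     1081 gggacctgcc acggcgaatt gatgctaccg gcgagccaca ctgtgctagc aggttaccat
     1141 cgagacagaa aatctccacg tttctgggtc gccccgtttt tattgaatat gggggtcggg
     1201 gcgggcacca gcaacggcct tttgcttttc gacgcgtcgt cgcttcacca gcccccccac
     1261 cttgatttag atggagatca agagcgtgtg agcttgctca ataggagcac ccgcacccta
     1321 ctcactaact ctagaatccg actcctcatc tacactaagt cctgggcatc cgatgcgaat
     1381 gcctttccga cgtcatatag gataccgaca catagaggac tcttcatctg tccggggagg
     1441 attacatgca caagtagttc cagcctgttc cttcccaggt tgggaccggt caagccggtc
     1501 ctggggcctg cgcggtgtgg gaacaatata cttacaccca ctaacgtgcc aagcgctgtt
     1561 agagtcctca gggtaggtca aagcattatc ctaataaagg attacgctgg ttcgccggga
     1621 cacggggagc ggacagtgcc agatacggcc ctcgcatctc cgaacctggt cgctactcct
     1681 tgttcactgt acgcgatgca tctcgactta gcgcctcgaa attcacacgt agtctctaaa
     1741 cctttctgtc taagttccac atccgcatgc cagcgagtgt cgcctatacc cggacggcgg
     1801 ccggataaca acacccttaa cataacttcg tataatgtat gctatacgaa gttataagac
     1861 tagctctctg taatgcccga ccaacagtgg gaggacatca tgaaggtaac gacgccatcc
     1921 tggagccaca cgccgccgaa cactaacaca ctcatagcgg ttcggcaagt ggtaatatcc
     1981 ctcgaccgaa ggcttacctt gcagccctag cccagtgaga ttttatgccg aagtatcgta
     2041 caggcctacc agtgaaagtt gtctctaagc tggagagaaa ggtcttaact tcattctcat
     2101 gctcaggctg tgattttttt acgctgacta ggctaacccc acaaaacaag ggcaaatgat
     2161 catcgggctt agttgggcat ggctcgaaac agacacaagt tcgtgtagga ctaacatcat
     2221 cttattgctt ggcgttcagc gaaacaaact gtggcatcgg cctaagggaa cccaactgac
     2281 ggaaagagta tcgcctagac accggcaaca tgaatgtcaa gccactctgc gatcagatga
     2341 tcgaataaga tctaggtgcc tccatagtga taaatgggtg tcacgcgaac tttcatcaca
     2401 ctgcagagca ggtgtaccat cgtgccgttc tggcggcata agattcggca agtgtaccaa
     2461 atgcggctac tcgacacgta aactgtccag tccatttggc ggaaggggtc tcagtggcgc
     2521 gagcgctctt tcccgttcca tgaaaagctc cccttttaca gttcgataca tttatataag
     2581 gcgccacgtc cgccacagaa atgtgtctga caggtatcaa acgatggcag ttcaaggtag
     2641 agcgaatcac tctgccaacc atccatgtgt gcttccagct cgatcgtgcc agaaggccga
     2701 ccctggtcaa tgcctacttt ctcgcgagcg cactcttccc gactcggtac attgggtaaa
     2761 tctggctggt ccggagggag aaataccatc tgtgattgcc gtaacggaga atctgtccct
     2821 taggaacctg ttataaccat ttaccaagat cctcttttcc gacagggacg cagtttacca
     2881 actcacaagt ttcaaagtct taggcaccgc gaagaggtag agtttttaca tcacgcgacg
     2941 aagaaaaacg gaatgatcag aatacccgca gagacctgat tacgctataa cttcgtataa
     3001 tgtatgctat acgaagttat ccggcgcgcc ctcgaggttt aaaccctttt ggacgcgaaa
     3061 aacacgtggc gacgggccgc ccgatcgcag cccggggggg gacgaaaacc tggagcggtc
     3121 tgtggcgagc gtctcttctt cttggactgg aactacaagg gctaacgatc cccaccacag
     3181 ggacaggtcg ccaagtttag gcggccactt ccatcgatct actc
//
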