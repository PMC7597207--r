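{
  "operons": {
    "flhDC": {
      "sequence": "GCAGCAGGGCGTCCTAAATATGCGTGAGCTCTACTACATCGGTAGTCGTCAGCCTCCACGATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTAGGCAATCTAACTCTTGTGAAGATATGTCAACCATCTAAAGGGGAAAAGGCAAGAGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCTTGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGCCGAGAACGCAAGGCC",
      "promoter": {
        "basal": 0.02,
        "sites": []
      },
      "genes": {
        "flhD": {
          "aa_seq": "LWHCRIDIRINWYIVRGSEMGCEGMITQEDPKIPRKCNIL",
          "rbs_affinity": 0.2
        },
        "flhC": {
          "aa_seq": "QISVFGDKSISVVIGLPHNGESTMPNVATANMSCKTIKKYQMYIV",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 285
    },
    "flgAMN": {
      "sequence": "TAGGTGGAGAAATGGGTACGGACAAGGACGATGTCACCCTATTTGCAAACAGCGCTGTAGACTCCGAATGACCTTTTTCAACTTTGTCCGCAATAATGTAACCCACCTATTTTGCCCTGGCACATCAAGACGAACCGGTATAAAACAACATAAACGTTGAACCACTATGCTCTGCTTCATTTAATCTTGCGGATTCCAAATCAAGGAGACGATATCACCGATGTC",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FlhDC",
            "role": "activator",
            "threshold": 20,
            "weight": 0.05
          }
        ]
      },
      "genes": {
        "flgM": {
          "aa_seq": "SHLWAKHETGEFEVSRKCYHAASYCKLTYM",
          "rbs_affinity": 0.2
        },
        "flgN": {
          "aa_seq": "KTTINEPLWCDLARMNFCLRDNSLECAVPYPPLQP",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 225
    },
    "flgBCD": {
      "sequence": "CAAAGGGTATACTGGTCACTTTGTGACAGAACTTAGTGTCACGAATTGTCAGGTCGCTCTGAACTGTACCGGCTAAAAGAATCGTACCCATGATTCGATCCCGTGGCGAGATGTGCTTAAATGGCCCGCGCAACTGGCCAAGTTTACTTCTACGACGGAAGACGACAAAGGGTCCTCCCACCTGTAATCAGTAACTGATTCATACATTGTCCCTTTCGTGGCCTAGTCAGGCATTGTCAAGTGAGCATCCTCACCAGTGTTAATGTGATTAATTGGGCCGAGAGGCCCGGATATACTGATTAGCGGACCTGTAGTACGTTCCATGGTCCGTTTTACCTGGGACTAGCACAGCGCGAGTACTAAAAGGAACTATGTAAGATGGACAACGAC",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FlhDC",
            "role": "activator",
            "threshold": 35,
            "weight": 0.05
          }
        ]
      },
      "genes": {
        "flgB": {
          "aa_seq": "YFYMTQQARKPQAALGPAIIGFGVITKYWACDPCKRDLNT",
          "rbs_affinity": 0.2
        },
        "flgC": {
          "aa_seq": "MEECMSLRLEGVWYWNDDVMGPRDKKQPPVPYGNRIVMGE",
          "rbs_affinity": 0.2
        },
        "flgD": {
          "aa_seq": "HWCDDIHVMTEDYWDWCRFPCGYSSEYIHGLTEHVQLMGV",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 390
    },
    "fliFGH": {
      "sequence": "CCATTCTTAACCCTGTCCGTATGATCTCCCCGATGGCGCACGGTCCTCCCTTGATCTCCGTCTCAATGAGGTCTAGTGAATGAAGATTGCAGAGCTGATTTCCGCGTGTTCTGACAGTGCGATCATATCGAAAGTTATGACAAAGGTCGCTCCACCCCTTACCGCAATAAGCCTGAAGTCCGTTTGATTCGGTGACGCGTCCAGGTTGCACTGGGTAAGTCCAAAGGGATTCACATCAATCGTTACTTGATACTAAATTTCCAGAATATTTAGGAGACCAATCCGGGCGCCTAGGGGTGTATCCTGTTGTCCCGCAATCTTGACGTGGCAATATGATGCAGTTCAACACCCATGCCGCTGTCCACGCCGTCCTTAATGCGTCCGAGTTGA",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FlhDC",
            "role": "activator",
            "threshold": 50,
            "weight": 0.05
          }
        ]
      },
      "genes": {
        "fliF": {
          "aa_seq": "GDHENAFCGEMIWQSNFSMSYTEYECSIYVVIRLGRPSLSRENPDNYVPS",
          "rbs_affinity": 0.2
        },
        "fliG": {
          "aa_seq": "YARCKTMSAIPHNVNGCCWELAYTMFAWFRMKASFYMLMR",
          "rbs_affinity": 0.2
        },
        "fliH": {
          "aa_seq": "TRIQGSDNVNRHWDDTPNWLWHKGEFCLDN",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 390
    },
    "fliAZY": {
      "sequence": "CGCGGCACTAATGTCCGTTCAGTTGGTATATGGCACGGTAGACAGTGAAACGTGAACGGTGTGGACATCACACCCCATAGGCCTACCACGCGGCTCTTGTTTGCAAACCAAGCTCCCTGACTAAGTACCAAAAGCATAGAGGCAGGGTATTAGTTGGACGAACGGTTACTGAAGAGGTATAATGTTCCAGACGCCCAGACGAACGAATAGGCGTCCGATCTCCCAGTTCCGAACTGGTTA",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FlhDC",
            "role": "activator",
            "threshold": 65,
            "weight": 0.05
          }
        ]
      },
      "genes": {
        "fliA": {
          "aa_seq": "YTSLECHDFRPPVQPEQIYRGDPELDALMDFTKSEWPQRY",
          "rbs_affinity": 0.2
        },
        "fliZ": {
          "aa_seq": "NIYQKPIYSIWWLNIVGHRQYRVQRIEQKA",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 240
    },
    "fliC": {
      "sequence": "GCTACACGTTTTGGGTCTATCAGGACGTCAGTTGAGAATTCGAACTACGGTTGTCAGACATATTATGAGCTTATTGATGCTCCAAAGGGCATAGCTGATATGAGGACGAGGACATGCTAGCGTGCGCTGCTGGATCTTTAAAGGCGTGCCCTTAATTATTGAGACTCAATCGACTAGTTTGTGCAAAAAGAGCTGTCCGAGCTAACGTAC",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FliA",
            "role": "activator",
            "threshold": 20,
            "weight": 0.08
          }
        ]
      },
      "genes": {
        "fliC": {
          "aa_seq": "CMTQPCDYHAELTTPLCCPLCFILDPQAQKAWAAFTQHKNKSCQRQYNHKDMSHSYHNCT",
          "rbs_affinity": 0.3
        }
      },
      "terminator": 210
    },
    "motAB_cheAW": {
      "sequence": "ACCAAGTTGGGGTGGCGCCACTAAACAAGTGAGGGTGGGTCTGGTTTACCGCGTATTCGGGTCCGCAGAATTTGGTTTGGTAGATGGAGCTCCACGATAGACCGGCTCTAAACTTTTCAGGGCATAAATCGGCCACGAATACTTCTACCTGAGATAGGGCGCAGTGATGGTGAAGGGACGCCGTCGTTTCTCATGGCACAGTCCATGGGTCAGTCCTACAACCCGCCTCACCTTCAGAGTTAACAATCAGGAGCCGTGGTGTTCACAATACCAGTTCCCCCAGTATATTTAACACTGTTTGAACCCTGACAAGTCCAGTTCCTTTCGGCGAATAGGTTCGTTGTGTTTTAATTGGATCTGTTCCTTGCCCATTTGACGAAGTCATTATAGAAGTTTCCGATCAGACTAAGTAGCGGCCATCGCCGAGGCTAAGCCAACTCTCTGGCAGTCAGACTTCTTACCCTTCTTTTACGGCGAAAT",
      "promoter": {
        "basal": 0,
        "sites": [
          {
            "tf": "FliA",
            "role": "activator",
            "threshold": 20,
            "weight": 0.08
          }
        ]
      },
      "genes": {
        "motA": {
          "aa_seq": "AQFYCFQHEIKWWGEMNWMQSSPLPTWGNHIRPVMEEDVV",
          "rbs_affinity": 0.2
        },
        "motB": {
          "aa_seq": "PTIWEEFRGKCDPCNYCIFRRTLPGKFENNLNAVEKHTWL",
          "rbs_affinity": 0.2
        },
        "cheA": {
          "aa_seq": "SCLSAWKLDEYNVDDTDQYADDGYTEINMANYQDLPLQRF",
          "rbs_affinity": 0.2
        },
        "cheW": {
          "aa_seq": "DPIRPIKKHSLIQFICSKMHIFYWKAYAKP",
          "rbs_affinity": 0.2
        }
      },
      "terminator": 480
    }
  },
  "complexation": {
    "cx_FlhDC": {
      "stoich": {
        "flhD": -1,
        "flhC": -1,
        "FlhDC": 1
      },
      "rate": 1000
    },
    "cx_FlgM_FliA": {
      "stoich": {
        "flgM": -1,
        "fliA": -1,
        "FlgM_FliA": 1
      },
      "rate": 1000
    },
    "cx_basal_body": {
      "stoich": {
        "flgB": -1,
        "flgC": -1,
        "flgD": -1,
        "fliF": -1,
        "fliG": -1,
        "fliH": -1,
        "basal_body": 1
      },
      "rate": 1000
    },
    "cx_flagellum": {
      "stoich": {
        "basal_body": -1,
        "fliC": -4,
        "motA": -1,
        "motB": -1,
        "flagellum": 1
      },
      "rate": 1000
    }
  },
  "polymerases": {
    "rnap": 10,
    "ribosomes": 20
  }
}
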