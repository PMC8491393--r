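{
  "version": "seed-1",
  "drugs": [
    {
      "name": "dabrafenib",
      "drug_class": "small_molecule",
      "targets": [
        "BRAF"
      ],
      "notes": "BRAF inhibitor"
    },
    {
      "name": "trametinib",
      "drug_class": "small_molecule",
      "targets": [
        "MAP2K1",
        "MAP2K2",
        "BRAF",
        "KRAS",
        "NRAS"
      ],
      "notes": "MEK inhibitor; MEK is the immediate downstream effector of BRAF/RAS"
    },
    {
      "name": "trastuzumab",
      "drug_class": "antibody",
      "targets": [
        "ERBB2"
      ],
      "notes": "anti-HER2 antibody"
    },
    {
      "name": "pertuzumab",
      "drug_class": "antibody",
      "targets": [
        "ERBB2"
      ],
      "notes": "anti-HER2 dimerization antibody"
    },
    {
      "name": "erdafitinib",
      "drug_class": "small_molecule",
      "targets": [
        "FGFR1",
        "FGFR2",
        "FGFR3",
        "FGFR4"
      ],
      "notes": "pan-FGFR inhibitor"
    },
    {
      "name": "erlotinib",
      "drug_class": "small_molecule",
      "targets": [
        "EGFR"
      ],
      "notes": "EGFR inhibitor"
    },
    {
      "name": "cetuximab",
      "drug_class": "antibody",
      "targets": [
        "EGFR"
      ],
      "notes": "anti-EGFR antibody"
    },
    {
      "name": "alpelisib",
      "drug_class": "small_molecule",
      "targets": [
        "PIK3CA"
      ],
      "notes": "PI3K-alpha inhibitor"
    },
    {
      "name": "everolimus",
      "drug_class": "small_molecule",
      "targets": [
        "MTOR",
        "PIK3CA",
        "AKT1",
        "PTEN",
        "TSC1",
        "TSC2"
      ],
      "notes": "mTOR inhibitor; mTOR is downstream of PI3K/AKT/PTEN/TSC"
    },
    {
      "name": "palbociclib",
      "drug_class": "small_molecule",
      "targets": [
        "CDK4",
        "CDK6",
        "CCND1",
        "CDKN2A"
      ],
      "notes": "CDK4/6 inhibitor; downstream of cyclin D1 and CDKN2A loss"
    },
    {
      "name": "crizotinib",
      "drug_class": "small_molecule",
      "targets": [
        "ALK",
        "MET",
        "ROS1"
      ],
      "notes": "ALK/MET/ROS1 inhibitor"
    },
    {
      "name": "larotrectinib",
      "drug_class": "small_molecule",
      "targets": [
        "NTRK1",
        "NTRK2",
        "NTRK3"
      ],
      "notes": "TRK inhibitor"
    },
    {
      "name": "pazopanib",
      "drug_class": "small_molecule",
      "targets": [
        "KDR",
        "FLT1",
        "FLT4",
        "KIT",
        "PDGFRA",
        "PDGFRB"
      ],
      "notes": "multikinase VEGFR inhibitor"
    },
    {
      "name": "bevacizumab",
      "drug_class": "antibody",
      "targets": [
        "VEGFA"
      ],
      "notes": "anti-VEGF-A antibody"
    },
    {
      "name": "carboplatin",
      "drug_class": "platinum_chemo",
      "targets": [],
      "notes": "platinum agent"
    },
    {
      "name": "olaparib",
      "drug_class": "parp_inhibitor",
      "targets": [],
      "notes": "PARP inhibitor"
    },
    {
      "name": "letrozole",
      "drug_class": "hormone_modulator",
      "targets": [],
      "notes": "aromatase inhibitor"
    },
    {
      "name": "enzalutamide",
      "drug_class": "hormone_modulator",
      "targets": [],
      "notes": "androgen receptor antagonist"
    },
    {
      "name": "pembrolizumab",
      "drug_class": "checkpoint_inhibitor",
      "targets": [
        "PDCD1",
        "CD274"
      ],
      "notes": "anti-PD-1; CD274 amplification treated as a direct genomic target"
    },
    {
      "name": "nivolumab",
      "drug_class": "checkpoint_inhibitor",
      "targets": [
        "PDCD1",
        "CD274"
      ],
      "notes": "anti-PD-1"
    },
    {
      "name": "gemcitabine",
      "drug_class": "cytotoxic_other",
      "targets": [],
      "notes": "nucleoside analogue"
    },
    {
      "name": "paclitaxel",
      "drug_class": "cytotoxic_other",
      "targets": [],
      "notes": "taxane"
    }
  ],
  "synergy_pairs": [
    {
      "drug_a": "dabrafenib",
      "drug_b": "trametinib",
      "shared_target": "BRAF"
    },
    {
      "drug_a": "pertuzumab",
      "drug_b": "trastuzumab",
      "shared_target": "ERBB2"
    }
  ],
  "special_rules": [
    {
      "rule_id": "brca_platinum_parp",
      "trigger_genes": [
        "BRCA1",
        "BRCA2",
        "ATM",
        "PALB2",
        "BARD1",
        "CHEK2"
      ],
      "satisfying_classes": [
        "platinum_chemo",
        "parp_inhibitor"
      ],
      "satisfying_targets": [],
      "enabled": true
    },
    {
      "rule_id": "tp53_vegf",
      "trigger_genes": [
        "TP53"
      ],
      "satisfying_classes": [],
      "satisfying_targets": [
        "VEGFA",
        "KDR",
        "FLT1",
        "FLT4"
      ],
      "enabled": true
    }
  ]
}
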