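[
  {"gene_id": "Phe",  "start": 577,   "end": 647,   "molecule_sense_is_reference_strand": true},
  {"gene_id": "Val",  "start": 1602,  "end": 1670,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Leu",  "start": 3230,  "end": 3304,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Ile",  "start": 4263,  "end": 4331,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Gln",  "start": 4329,  "end": 4400,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Met",  "start": 4402,  "end": 4469,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Trp",  "start": 5512,  "end": 5579,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Ala",  "start": 5587,  "end": 5655,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Asn",  "start": 5657,  "end": 5729,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Cys",  "start": 5761,  "end": 5826,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Tyr",  "start": 5826,  "end": 5891,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Ser",  "start": 7446,  "end": 7514,  "molecule_sense_is_reference_strand": false},
  {"gene_id": "Asp",  "start": 7518,  "end": 7585,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Lys",  "start": 8295,  "end": 8364,  "molecule_sense_is_reference_strand": true},
  {"gene_id": "Gly",  "start": 9991,  "end": 10058, "molecule_sense_is_reference_strand": true},
  {"gene_id": "Arg",  "start": 10405, "end": 10469, "molecule_sense_is_reference_strand": true},
  {"gene_id": "His",  "start": 12138, "end": 12206, "molecule_sense_is_reference_strand": true},
  {"gene_id": "Ser2", "start": 12207, "end": 12265, "molecule_sense_is_reference_strand": true},
  {"gene_id": "Leu2", "start": 12266, "end": 12336, "molecule_sense_is_reference_strand": true},
  {"gene_id": "Glu",  "start": 14674, "end": 14742, "molecule_sense_is_reference_strand": false},
  {"gene_id": "Thr",  "start": 15888, "end": 15953, "molecule_sense_is_reference_strand": true},
  {"gene_id": "Pro",  "start": 15956, "end": 16023, "molecule_sense_is_reference_strand": false}
]
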