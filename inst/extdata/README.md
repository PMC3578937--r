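# External data expected here

The package ships no sequence data. To run the full-region analysis on the
deposited resequencing data (GenBank KC460991-KC461010 plus the outgroup
reference), download the sequences, align them (e.g. with MAFFT/MUSCLE), and
place two files in this directory before installing:

* `flo2_region_alignment.fasta` — the 20,011-column multi-FASTA alignment of
  the 24 ingroup lines and the outgroup sequence;
* `flo2_region_alignment_popmap.tsv` — tab-separated with header
  `label<TAB>tag`, mapping every FASTA record to `EU`, `AF`, or `outgroup`.

The corresponding acceptance test then verifies the regional diversity
contrast and fixed-difference counts against the reported values.
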