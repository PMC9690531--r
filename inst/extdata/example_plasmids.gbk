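LOCUS       pDEMO1                 12000 bp    DNA     circular BCT 01-JAN-2022
DEFINITION  Synthetic demonstration plasmid 1.
ACCESSION   pDEMO1
SOURCE      Klebsiella pneumoniae
  ORGANISM  Klebsiella pneumoniae
            Bacteria; Proteobacteria; Gammaproteobacteria.
FEATURES             Location/Qualifiers
     source          1..12000
                     /organism="Klebsiella pneumoniae"
                     /host="Homo sapiens"
                     /isolation_source="clinical urine sample"
     CDS             100..400
                     /locus_tag="PD1_001"
                     /product="MerR family transcriptional regulator"
     CDS             complement(900..1500)
                     /locus_tag="PD1_002"
                     /product="mercuric reductase MerA"
     CDS             join(2000..2200,2300..2600)
                     /locus_tag="PD1_003"
                     /product="hypothetical protein spanning a
                     two-exon join location"
ORIGIN
//
LOCUS       pDEMO2                  8000 bp    DNA     linear   BCT 01-JAN-2022
DEFINITION  Synthetic demonstration plasmid 2.
ACCESSION   pDEMO2
SOURCE      Shewanella baltica
  ORGANISM  Shewanella baltica
            Bacteria; Proteobacteria; Gammaproteobacteria.
FEATURES             Location/Qualifiers
     source          1..8000
                     /organism="Shewanella baltica"
     CDS             complement(join(500..700,800..1000))
                     /locus_tag="PD2_001"
                     /product="compound complement location"
     CDS             3000..3900
                     /locus_tag="PD2_002"
                     /product="sulfonamide-resistant dihydropteroate
                     synthase Sul1"
ORIGIN
//
LOCUS       pDEMO3                  5000 bp    DNA     linear   BCT 01-JAN-2022
DEFINITION  Synthetic demonstration plasmid 3 (no CDS metadata qualifiers).
ACCESSION   pDEMO3
SOURCE      Escherichia coli
  ORGANISM  Escherichia coli
            Bacteria; Proteobacteria; Gammaproteobacteria.
FEATURES             Location/Qualifiers
     source          1..5000
                     /organism="Escherichia coli"
                     /host="Sus scrofa"
     CDS             <1..660
                     /locus_tag="PD3_001"
                     /product="partial CDS with fuzzy start"
ORIGIN
//
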