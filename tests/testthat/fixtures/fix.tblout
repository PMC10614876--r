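# target name        accession  query name           accession  hmmfrom hmm to alifrom  ali to envfrom  env to  sq len strand   E-value  score  bias  description of target
#------------------- ---------- -------------------- ---------- ------- ------- ------- ------- ------- ------- ------- ------ --------- ------ ----- ---------------------
fix_genome           -          fix_phage            -                1    1200    3001    4200    3001    4200   10400    +           0 1286.8   3.2  -
fix_genome           -          fix_phage            -                1    1200    7400    6201    7400    6201   10400    -           0 1286.8   3.2  -
#
# Program:         nhmmer
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SEARCH
# Query file:      fix_phage.fasta
# Target file:     fix_genome.fasta
# Option settings: nhmmer -o /dev/null --tblout fix.tblout fix_phage.fasta fix_genome.fasta 
# Current dir:     /root/pkg/scratch
# Date:            Fri Sep 25 00:08:32 2026
# [ok]
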