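>chr10:38932814-38933047 centromeric repeat (hg38)
ACTAGGGTAGGTAATTTCATCTCAGTCTTATGCAGGTACCTTTTCTCAGGATCTCAGGAA
TGCAGACTTCTCACACTTCTGTTCTTTTCCTGGCTGTGTTGGTGAGCTCAGTGATATTCC
TCCATCACCTTCAAGAGCAGTTTTGTTTTGTTTTTCCTGTTTTCATACTCCCAGCATCAG
GAGTGTTCTAGGTGTGTCAGTTTTTGTTACCTTCCCCTACATATTAAGTGGAA
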