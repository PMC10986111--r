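loci:
- locus: DYS456
  allele_min: 13.0
  allele_max: 18.0
  copies: 1
- locus: DYS389I
  allele_min: 9.0
  allele_max: 17.0
  copies: 1
- locus: DYS390
  allele_min: 17.0
  allele_max: 28.0
  copies: 1
- locus: DYS389II
  allele_min: 23.0
  allele_max: 34.0
  copies: 1
- locus: DYS458
  allele_min: 14.0
  allele_max: 20.0
  copies: 1
- locus: DYS19
  allele_min: 10.0
  allele_max: 19.0
  copies: 1
- locus: DYS385
  allele_min: 7.0
  allele_max: 25.0
  copies: 2
- locus: DYS393
  allele_min: 8.0
  allele_max: 16.0
  copies: 1
- locus: DYS391
  allele_min: 6.0
  allele_max: 14.0
  copies: 1
- locus: DYS439
  allele_min: 8.0
  allele_max: 15.0
  copies: 1
- locus: DYS635
  allele_min: 20.0
  allele_max: 26.0
  copies: 1
- locus: DYS392
  allele_min: 7.0
  allele_max: 18.0
  copies: 1
- locus: YGATAH4
  allele_min: 8.0
  allele_max: 13.0
  copies: 1
- locus: DYS437
  allele_min: 13.0
  allele_max: 17.0
  copies: 1
- locus: DYS438
  allele_min: 8.0
  allele_max: 13.0
  copies: 1
- locus: DYS448
  allele_min: 17.0
  allele_max: 27.0
  copies: 1
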