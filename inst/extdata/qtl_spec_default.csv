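chrom,snp_index,effect,class
1,60,0.06411,minor
1,186,-0.076787,minor
1,311,-0.369887,major
1,437,0.027313,minor
1,563,-0.090234,major
1,689,0.085873,minor
1,814,-0.076764,minor
1,940,0.082278,minor
2,60,-0.029907,minor
2,207,0.033446,minor
2,353,-0.046329,minor
2,500,-0.079309,minor
2,647,-0.064571,minor
2,793,0.204759,major
2,940,0.330761,major
3,60,0.038926,minor
3,207,0.28355,major
3,353,-0.065433,minor
3,500,-0.023784,minor
3,647,-0.052833,minor
3,793,0.265683,major
3,940,-0.049501,minor
4,60,0.274381,major
4,207,0.030619,minor
4,353,0.027045,minor
4,500,0.166294,major
4,647,0.084068,minor
4,793,-0.04612,minor
4,940,0.24481,major
5,60,-0.149259,major
5,207,-0.035438,minor
5,353,-0.186709,major
5,500,-0.354554,major
5,647,0.054264,minor
5,793,0.276332,major
5,940,0.04234,minor
6,60,-0.048551,minor
6,207,-0.087121,major
6,353,-0.073589,minor
6,500,-0.054702,minor
6,647,0.216928,major
6,793,0.100626,minor
6,940,0.072398,minor
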