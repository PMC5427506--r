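species	anchored_loci	anchored_genes	singleton_loci	clustered_loci	clustered_genes	clusters_ge10	largest_cluster_size	largest_cluster_chrom
tomato	129	253	79	50	174	1	13	Chr4
potato	159	447	80	79	367	10	22	Chr4
pepper	138	260	88	50	172	1	13	Chr3
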