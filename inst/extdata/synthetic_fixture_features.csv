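"feature","value"
"fat_amount",382.5
"fat_amount_norm",42.5
"stroma_amount",326.75
"stroma_amount_norm",36.3055555555556
"epi_amount",190.75
"epi_amount_norm",21.1944444444444
"n_epi_regions",3
"epi_area_mean",63.5833333333333
"epi_area_median",63.25
"epi_area_sd",9.75427256812794
"epi_area_iq",9.75
"epi_area_max",73.5
"epi_ecc_mean",0.535812157825448
"epi_ecc_median",0.746508902690159
"epi_ecc_sd",0.467540275545743
"epi_ecc_iq",0.430463785393092
"epi_ecc_max",0.860927570786185
"voronoi_area_mean",300
"voronoi_area_median",244.5
"voronoi_area_sd",146.366833674846
"voronoi_area_iq",138.25
"voronoi_area_max",466
"ratio_epi_voronoi_mean",0.233792316865323
"ratio_epi_voronoi_median",0.258691206543967
"ratio_epi_voronoi_sd",0.0671726039091127
"ratio_epi_voronoi_iq",0.0636175501375882
"ratio_epi_voronoi_max",0.284960422163588
"ratio_epi_nonepi_mean",0.311583549659349
"ratio_epi_nonepi_median",0.348965517241379
"ratio_epi_nonepi_sd",0.110481018205254
"ratio_epi_nonepi_iq",0.105631419371519
"ratio_epi_nonepi_max",0.398523985239852
"delaunay_neighbors_mean",2
"delaunay_neighbors_median",2
"delaunay_neighbors_sd",0
"delaunay_neighbors_iq",0
"delaunay_neighbors_max",2
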