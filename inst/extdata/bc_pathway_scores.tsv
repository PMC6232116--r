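pathway	path_rank_score	n_communities	path_gene_score	path_score	communities
ERBB signaling pathway	0.815143	14	0.715853953	0.763886926	4 25 26 33 34 36 38 40 42 43 44 46 47 48
Prolactin signaling pathway	0.795867	15	0.72857406	0.761477386	4 6 11 33 34 36 38 39 40 42 43 44 46 47 48
mTOR signaling pathway	0.815500	4	0.687676019	0.748865671	4 36 42 44
p53 signaling pathway	0.735875	8	0.735254081	0.735564475	4 9 10 12 16 30 32 42
FOXO signaling pathway	0.787647	17	0.683991499	0.733991752	4 5 6 11 12 22 34 36 38 39 42 43 44 45 46 47 48
HIF-1 signaling pathway	0.796182	11	0.673983105	0.7325388	2 4 5 22 34 36 38 41 42 45 46
VEGF signaling pathway	0.799750	16	0.663653015	0.728530369	4 6 11 25 26 33 34 36 38 42 43 44 45 46 47 48
Homologous recombination	0.689800	5	0.744804648	0.716774892	9 24 27 30 32
Thyroid hormone signaling pathway	0.801071	14	0.626992865	0.708707323	4 5 10 20 28 33 34 35 36 37 43 44 46 47
Adherens junction	0.794533	15	0.630206366	0.70761569	4 5 11 25 26 28 33 36 38 40 43 44 46 47 48
Adipocytokine signaling pathway	0.831000	6	0.596127825	0.703833945	4 5 10 42 46 48
TNF signaling pathway	0.790667	12	0.621398946	0.700941819	4 6 11 16 36 39 41 42 45 46 47 48
Neurotrophin signaling pathway	0.794800	15	0.61762929	0.700636681	4 6 11 25 34 36 38 39 40 43 44 45 46 47 48
B cell receptor signaling pathway	0.839583	12	0.583361014	0.699842972	4 33 34 36 38 39 42 44 45 46 47 48
Fc epsilon RI signaling pathway	0.785500	14	0.623089264	0.699597468	4 6 11 25 33 34 36 38 40 43 44 46 47 48
Cell cycle	0.705455	11	0.681447933	0.693347346	4 5 9 10 12 13 22 29 30 32 47
Insulin resistance	0.854000	4	0.560416943	0.691806381	4 5 42 46
PI3K-AKT signaling pathway	0.802462	13	0.584009347	0.68457654	4 22 26 33 34 35 36 38 42 44 45 46 47
Focal adhesion	0.800353	17	0.576200699	0.679090513	4 11 22 25 26 33 34 36 38 40 42 43 44 45 46 47 48
AMPK signaling pathway	0.817000	4	0.562233667	0.677749885	4 10 42 44
NOD-like receptor signaling pathway	0.786500	10	0.580649858	0.675781853	4 6 11 36 39 41 43 46 47 48
Sphingolipid signaling pathway	0.782615	13	0.576929156	0.671947642	4 6 11 33 34 35 36 43 44 45 46 47 48
T cell receptor signaling pathway	0.776857	14	0.577623933	0.669874076	4 6 11 25 26 34 36 38 39 40 44 46 47 48
JAK-STAT signaling pathway	0.830000	6	0.523496172	0.659167523	4 10 34 42 44 46
RAS signaling pathway	0.780833	18	0.548420257	0.654388889	4 8 11 22 25 26 33 34 36 38 40 42 43 44 45 46 47 48
Mismatch repair	0.720200	5	0.582186126	0.647526407	9 15 24 30 32
Estrogen signaling pathway	0.731111	18	0.559789644	0.639740908	1 3 4 6 14 20 31 34 35 36 38 39 40 41 44 45 46 47
MAPK signaling pathway	0.777053	19	0.514896219	0.63253574	4 6 8 11 20 22 25 26 34 36 38 39 42 43 44 45 46 47 48
RAP1 signaling pathway	0.736048	21	0.539811636	0.630338853	1 4 6 11 14 22 25 26 31 33 34 35 36 38 42 43 44 45 46 47 48
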