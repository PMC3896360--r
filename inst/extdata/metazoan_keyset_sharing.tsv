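group	Annelida	Chelicerata	Coelenterata	Crustacea	Echinodermata	Hexapoda	Mollusca	Nematoda	Platyhelminthes	Porifera	Vertebrate
Annelida	4656	721	308	748	669	782	641	330	367	510	611
Chelicerata	84.5	2987	349	911	718	1091	611	534	579	559	511
Coelenterata	91.8	88.3	2642	308	384	328	274	193	259	777	291
Crustacea	83.9	69.5	88.3	2827	674	1117	612	342	438	500	552
Echinodermata	85.6	76	85.5	71.2	3340	682	491	343	503	594	685
Hexapoda	83.2	63.5	87.6	60.5	79.6	3197	559	454	464	549	576
Mollusca	86.2	79.5	89.6	78.4	85.3	82.5	1956	291	345	418	428
Nematoda	92.9	82.1	92.7	87.9	89.7	85.8	85.1	2545	485	309	195
Platyhelminthes	92.1	80.6	90.2	84.5	84.9	85.5	82.4	80.9	4326	448	223
Porifera	89.1	81.3	70.6	82.3	82.2	82.8	78.6	87.9	89.6	4198	435
Vertebrate	86.9	82.9	89	80.5	79.5	82	78.1	92.3	94.9	89.6	3055
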