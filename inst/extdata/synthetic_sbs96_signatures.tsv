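Type	sim_bg	sim_hd	sim_ox
A[C>A]A	0.0115531039779358	0.0121639756720487	0.007026
A[C>A]C	0.00812407311665805	0.00876498247003506	0.004276
A[C>A]G	0.0146861321751896	0.00893098213803572	0.005706
A[C>A]T	0.0130571175140576	0.0134189731620537	0.003251
C[C>A]A	0.00606405457649119	0.0141289717420565	0.001862
C[C>A]C	0.00990408913680223	0.0156449687100626	0.006347
C[C>A]G	0.0121491093419841	0.00703998592002816	0.005335
C[C>A]T	0.0119401074609671	0.008000983998032	0.003629
G[C>A]A	0.00660405943653493	0.0116629766740467	0.002128
G[C>A]C	0.00789207102863926	0.00843598312803374	0.002663
G[C>A]G	0.00935108415975744	0.0110919778160444	0.004871
G[C>A]T	0.0103670933038397	0.0100709798580403	0.004256
T[C>A]A	0.00725006525058726	0.0057239885520229	0.005028
T[C>A]C	0.00857107713969426	0.00810998378003244	0.003574
T[C>A]G	0.00560805047245425	0.00860298279403441	0.00559
T[C>A]T	0.0132611193500742	0.00820798358403283	0.004459
A[C>G]A	0.0109290983618853	0.00233699532600935	0
A[C>G]C	0.00832407491667425	0.00218399563200874	0
A[C>G]G	0.0144721302491722	0.0030739938520123	0
A[C>G]T	0.00520204681842137	0.00348199303601393	0
C[C>G]A	0.0147931331381982	0.00180699638600723	0
C[C>G]C	0.00967308705778352	0.00148799702400595	0
C[C>G]G	0.0122181099629897	0.00218099563800872	0
C[C>G]T	0.00670306032754295	0.00172999654000692	0
G[C>G]A	0.013000117001053	0.00254099491801016	0
G[C>G]C	0.00757606818461366	0.0020749958500083	0
G[C>G]G	0.0102880925928333	0.0028249943500113	0
G[C>G]T	0.00769406924662322	0.00257999484001032	0
T[C>G]A	0.00404803643232789	0.00304099391801216	0
T[C>G]C	0.0121961097649879	0.00335699328601343	0
T[C>G]G	0.0167811510303593	0.00289599420801158	0
T[C>G]T	0.0135141216270946	0.00240299519400961	0
A[C>T]A	0.0104980944828503	0.0144499711000578	0.015122
A[C>T]C	0.0135661220950989	0.0129329741340517	0.009565
A[C>T]G	0.00530704776342987	0.0528458943082114	0.012728
A[C>T]T	0.0155001395012555	0.00855698288603423	0.011285
C[C>T]A	0.0148201333812004	0.0123079753840492	0.008018
C[C>T]C	0.00539404854643692	0.0134799730400539	0.017471
C[C>T]G	0.00980608825479429	0.0339529320941358	0.011254
C[C>T]T	0.0164211477903301	0.00900198199603601	0.015174
G[C>T]A	0.00753806784261058	0.0107929784140432	0.009309
G[C>T]C	0.0108960980648826	0.0110259779480441	0.010671
G[C>T]G	0.00716506448558037	0.0318129363741273	0.016655
G[C>T]T	0.00500804507240565	0.011503976992046	0.016805
T[C>T]A	0.0103380930428374	0.0105749788500423	0.008091
T[C>T]C	0.0178931610384493	0.0161939676120648	0.010751
T[C>T]G	0.00383803454231088	0.0364129271741457	0.016662
T[C>T]T	0.0087740789667107	0.0141529716940566	0.010439
A[T>A]A	0.0131411182700644	0.00215799568400863	0
A[T>A]C	0.0159651436862932	0.00129199741600517	0
A[T>A]G	0.00774606971462743	0.00110899778200444	0
A[T>A]T	0.0112621013589122	0.00291399417201166	0
C[T>A]A	0.00682406141655275	0.00195999608000784	0
C[T>A]C	0.00653905885152966	0.00170299659400681	0
C[T>A]G	0.0196151765365888	0.00289699420601159	0
C[T>A]T	0.0140271262441362	0.00121599756800486	0
G[T>A]A	0.00894208047872431	0.00222299555400889	0
G[T>A]C	0.0162951466563199	0.00145699708600583	0
G[T>A]G	0.0151791366122295	0.00197899604200792	0
G[T>A]T	0.00884207957871621	0.00158299683400633	0
T[T>A]A	0.0138471246241216	0.00134599730800538	0
T[T>A]C	0.0134781213030917	0.0024509950980098	0
T[T>A]G	0.0121591094319849	0.00228499543000914	0
T[T>A]T	0.00961408652677874	0.0014259971480057	0
A[T>C]A	0.0127941151470363	0.0365539268921462	0.2
A[T>C]C	0.00518004662041958	0.0271689456621087	0.007427
A[T>C]G	0.00821507393566542	0.0299289401421197	0.011307
A[T>C]T	0.0206971862746765	0.0313629372741255	0.008345
C[T>C]A	0.00792607133464201	0.0387719224561551	0.007873
C[T>C]C	0.0109540985868873	0.0304529390941218	0.011615
C[T>C]G	0.0118551066959603	0.0212739574520851	0.00783
C[T>C]T	0.00450104050936458	0.0247779504440991	0.005824
G[T>C]A	0.00987708889380005	0.0198569602860794	0.16
G[T>C]C	0.0213671923047307	0.0212309575380849	0.013466
G[T>C]G	0.0108000972008748	0.0221559556880886	0.004793
G[T>C]T	0.00511804606241456	0.027996944006112	0.13
T[T>C]A	0.00966808701278312	0.018500962998074	0.11
T[T>C]C	0.00673506061554554	0.0222319555360889	0.007931
T[T>C]G	0.0055740501664515	0.0290679418641163	0.007607
T[T>C]T	0.00950208551876967	0.0386669226661547	0.005983
A[T>G]A	0.0113601022409202	0.00126599746800506	0.002336
A[T>G]C	0.0166021494193448	0.00247799504400991	0.001616
A[T>G]G	0.00936308426775841	0.0017009965980068	0.002065
A[T>G]T	0.00596905372148349	0.00178199643600713	0.001332
C[T>G]A	0.00555404998644988	0.00223599552800894	0.001737
C[T>G]C	0.0133891205020845	0.00315199369601261	0.002114
C[T>G]G	0.0102020918188264	0.00243399513200974	0.002734
C[T>G]T	0.0052740474664272	0.00211199577600845	0.001729
G[T>G]A	0.0199941799476195	0.00139299721400557	0.001184
G[T>G]C	0.0130181171630545	0.0020259959480081	0.001708
G[T>G]G	0.00561405052645474	0.00126399747200506	0.001909
G[T>G]T	0.00842707584368259	0.00159799680400639	0.002077
T[T>G]A	0.00597505377548398	0.00170299659400681	0.002053
T[T>G]C	0.0121911097199875	0.00144599710800578	0.001821
T[T>G]G	0.0096690870217832	0.00130499739000522	0.001895
T[T>G]T	0.00659805938253444	0.00210399579200842	0.001688
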