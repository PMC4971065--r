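channel	A	B	C	D
Fp1	-0.0162945838	-0.2274096731	0.22837858087	-0.07325224777
Fpz	-0.1218521285	-0.1218521285	0.22837858087	0.02194259080
Fp2	-0.2274096731	-0.0162945838	0.22837858087	-0.07325224777
AF7	0.0477427608	-0.2346684504	0.17517061153	-0.08136849947
AF3	-0.0228600420	-0.1640656476	0.17517061153	0.05263469358
AFz	-0.0934628448	-0.0934628448	0.17517061153	0.14655436041
AF4	-0.1640656476	-0.0228600420	0.17517061153	0.05263469358
AF8	-0.2346684504	0.0477427608	0.17517061153	-0.08136849947
F7	0.0973760725	-0.2275231947	0.12196264220	-0.09057453344
F5	0.0567636641	-0.1869107863	0.12196264220	-0.01628044557
F3	0.0161512557	-0.1462983779	0.12196264220	0.09858847245
F1	-0.0244611527	-0.1056859695	0.12196264220	0.21390982399
Fz	-0.0650735611	-0.0650735611	0.12196264220	0.26363288421
F2	-0.1056859695	-0.0244611527	0.12196264220	0.21390982399
F4	-0.1462983779	0.0161512557	0.12196264220	0.09858847245
F6	-0.1869107863	0.0567636641	0.12196264220	-0.01628044557
F8	-0.2275231947	0.0973760725	0.12196264220	-0.09057453344
FT9	0.1433820158	-0.2082337856	0.06077347747	-0.10139659571
FT7	0.1082204356	-0.1730722055	0.06077347747	-0.04662173906
FC5	0.0730588555	-0.1379106253	0.06077347747	0.04595183834
FC3	0.0378972753	-0.1027490452	0.06077347747	0.16429086521
FC1	0.0027356952	-0.0675874651	0.06077347747	0.26895138503
FCz	-0.0324258849	-0.0324258849	0.06077347747	0.31130697456
FC2	-0.0675874651	0.0027356952	0.06077347747	0.26895138503
FC4	-0.1027490452	0.0378972753	0.06077347747	0.16429086521
FC6	-0.1379106253	0.0730588555	0.06077347747	0.04595183834
FT8	-0.1730722055	0.1082204356	0.06077347747	-0.04662173906
FT10	-0.2082337856	0.1433820158	0.06077347747	-0.10139659571
T7	0.1786011236	-0.1809964694	0.00224471121	-0.11102203628
C5	0.1336514245	-0.1360467703	0.00224471121	-0.05103908091
C3	0.0887017254	-0.0910970712	0.00224471121	0.05879667328
C1	0.0437520262	-0.0461473720	0.00224471121	0.18221926314
Cz	-0.0011976729	-0.0011976729	0.00224471121	0.23851869103
C2	-0.0461473720	0.0437520262	0.00224471121	0.18221926314
C4	-0.0910970712	0.0887017254	0.00224471121	0.05879667328
C6	-0.1360467703	0.1336514245	0.00224471121	-0.05103908091
T8	-0.1809964694	0.1786011236	0.00224471121	-0.11102203628
TP7	0.2058384398	-0.1457773616	-0.05628405506	-0.11928194300
CP5	0.1618864646	-0.1018253864	-0.05628405506	-0.07961296059
CP3	0.1179344895	-0.0578734112	-0.05628405506	-0.00984258275
CP1	0.0739825143	-0.0139214360	-0.05628405506	0.06648267508
CPz	0.0300305391	0.0300305391	-0.05628405506	0.10083482279
CP2	-0.0139214360	0.0739825143	-0.05628405506	0.06648267508
CP4	-0.0578734112	0.1179344895	-0.05628405506	-0.00984258275
CP6	-0.1018253864	0.1618864646	-0.05628405506	-0.07961296059
TP8	-0.1457773616	0.2058384398	-0.05628405506	-0.11928194300
P7	0.2251278489	-0.0997714183	-0.11747321979	-0.12613645906
P5	0.1845154405	-0.0591590099	-0.11747321979	-0.10559763213
P3	0.1439030321	-0.0185466015	-0.11747321979	-0.07384176978
P1	0.1032906237	0.0220658069	-0.11747321979	-0.04196083080
Pz	0.0626782153	0.0626782153	-0.11747321979	-0.02821473931
P2	0.0220658069	0.1032906237	-0.11747321979	-0.04196083080
P4	-0.0185466015	0.1439030321	-0.11747321979	-0.07384176978
P6	-0.0591590099	0.1845154405	-0.11747321979	-0.10559763213
P8	-0.0997714183	0.2251278489	-0.11747321979	-0.12613645906
PO7	0.2322731046	-0.0501381066	-0.17068118912	-0.13061362864
PO3	0.1616703018	0.0204646962	-0.17068118912	-0.10969331207
POz	0.0910674990	0.0910674990	-0.17068118912	-0.09503075727
PO4	0.0204646962	0.1616703018	-0.17068118912	-0.10969331207
PO8	-0.0501381066	0.2322731046	-0.17068118912	-0.13061362864
O1	0.2250143273	0.0138992380	-0.22388915845	-0.13386364488
Oz	0.1194567827	0.1194567827	-0.22388915845	-0.12547101190
O2	0.0138992380	0.2250143273	-0.22388915845	-0.13386364488
Iz	0.1379098170	0.1379098170	-0.25847433852	-0.13372531170
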