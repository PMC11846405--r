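product_name,manufacturer,normative,product_type,preliminary_score,final_score
"CBfarma—Espectro Completo—CBD 500 mg MCT (CBD 500 mg)/frasco 30 ml",CBFarma,N660,oil,52,68
"Nunature Labs—Espectro Completo—Canabidiol NuNature Oil (34,36 mg/ml)/frasco 30 ml",Nunature Labs,N327,oil,65,65
Extrato de Cannabis sativa Herbarium 43 mg/mL,Herbarium,N327,oil,62,62
Alliant CBD,Alliant,N660,oil,62,62
USAHemp CBD full spectrum,USA Hemp CBD,N660,oil,41,62
Alma CBD,CaniBrands Inc,N660,oil,61,61
"Canabidiol Greencare 23,75 mg/ml",Greencare,N327,extract,59,59
Extrato de Cannabis sativa Cann 10 Pharma 200 mg/ml,Cann 10 Pharma,N327,extract,59,59
"Canabidiol Mantecorp Farmasa 23,75 mg/ml",Mantecorp Farmasa,N327,oil,59,59
"Lazarus Naturals—Espectro Completo—Sleep + Melatonina Capsulas—(CBD 30 mg + CBG 10 mg + CBN 10 mg por cápsula)/frasco 40 cps",Lazarus Naturals,N660,capsule,57,57
Canabidiol Farmanguinhos,Farmanguinhos,N327,oil,56,56
Epidiolex,GW Pharmaceuticals,N660,oil,56,56
Belcher—Isolado—Canabidiol Belcher—(CBD 150 mg/ml)/frasco 10 ml,Belcher,N327,oil,55,55
Canabidiol Aura Pharma,Aura Pharma,N327,oil,52,52
Canabidiol Active Pharmaceutica 20 mg/ml,Active Caldic,N327,oil,52,52
Mevatyl,Ipsen,N327,spray,50,50
MEDTerra's CBD Oil,MEDTerra,N660,oil,50,50
Carmen’s Medicinals Full Spectrum Cannabinoids,Carmen’s Medicinals Full Spectrum,N660,oil,50,50
Elixinol—Espectro Amplo—Everyday Rapid Reset Liposome (CBD 1000 mg)/frasco 100 ml,Elixinol LCC,N660,oil,50,50
Alese CBD,Korasana,N660,oil,49,49
Epixann 10%,Caillon Hamonet,N660,oil,29,46
Eliv—Espectro Completo—CBD Starter—1500 mg CBD—30 ml,Korasana,N660,oil,45,45
Canna River—Isolado—Delta 8 Tincture (1000 mg)/frasco 15 ml,Canna River LCC,N660,tincture,45,45
Beyond Botanicals,Beyond Botanicals LLC,N660,oil,45,45
Neurogan CBD,Neurogan,N660,oil,43,43
Enecta CBD,Enecta,N660,oil,32,43
Canabidiol Collect (20 mg/ml),Collect,N327,oil,42,42
ECS Care,ECS Therapeutics LLC,N660,oil,42,42
Organic CBD Oil,Hempen Organic,N660,oil,42,42
Óleo CBD full spectrum—6000 mg,USA Hemp CBD,N660,oil,41,41
Verdemed CBD,Verdemed,N327,oil,41,41
Nuleaf Naturals CBD Oil,Nuleaf Naturals LLC,N660,oil,41,41
Cibdol,Cibdol bv,N660,oil,40,40
Prati-Donaduzzi—Isolado—Óleo de CBD 200 mg/ml (CBD 6000 mg)/frasco 30 ml,Prati-Donaduzzi,N327,oil,40,40
HempMeds—Espectro Competo—RSHO-BR—CBD Oil (CBD 3000 mg)/frasco 30 ml,Hemp Meds Px,N660,oil,39,39
Hemp & Olive,Green Gorilla,N660,oil,39,39
NanoLab CBD,NanoLab Nutrition LLC,N660,oil,38,38
Tegra EUROLINE CBD,Korasana,N660,oil,38,38
Endoca Hemp Oil,Endoca,N660,oil,37,37
Nordic Oil CBD,Nordic Health Group,N660,oil,36,36
Charlotte Web Hemp Extract,CW Botanicals,N660,extract,36,36
CBDAlchemy Oil,CBDAlchemy,N660,oil,26,36
FAB CBD,FAB Nutrition,N660,oil,35,35
Alivitta CBD,ALIVITTA LLC,N660,oil,35,35
Green Monkey CBD Oil 1500 mg,Green Monkey CBD Store,N660,oil,35,35
Cibadol Cannabidiol,Cibadol,N660,oil,35,35
Allandiol CBD,Biocase Brasil,N660,oil,34,34
Leaf CBD,Leafmed Care,N660,oil,32,32
Evona CBD,Hemp For Fitness LLC,N660,oil,32,32
Valenss Wellness CBD,Valenss Wellness,N660,oil,32,32
Provacan CBD,Ciitech,N660,oil,32,32
Isospec—Auttrum—Espectro Completo—Oil (CBD 1500 mg + CBG 1500 mg)/frasco 30 ml,Isospec Ltd,N660,oil,31,31
Golden CBD—Isolado—Slim THCV 500 mg (THCV 500 mg)/frasco 30 ml,Golden CBD,N660,oil,31,31
CannaBrasil,CannaBrasil,N327,extract,31,31
Cannamedic CBD Oil,Cannamedic B.V,N660,oil,30,30
CBD Vida—Nano-infused CBD,CBD Vida,N660,oil,29,29
Entourage CBD,The Native Hemp,N660,oil,29,29
MGC Pharma (CBD/THC),MGC Pharma,N660,oil,28,28
LGP Classic,Little Green Pharma,N660,oil,27,27
ELC CBD,Ease Labs,N327,oil,27,27
Verdecann Aceite CBD,Verdecann,N660,oil,26,26
EVR Hemp Oil CBD,EVR Premium Hemp Oil,N660,oil,26,26
Epifractan CBD (5%),Medicplast S/A,N660,oil,26,26
Sativida CBD,Sativida,N660,oil,25,25
Dixie Botanicals,Hemp Oil Hemp Meds Px,N660,oil,25,25
Cibdex Hemp CBD Complex,Hemp Meds Px,N660,oil,25,25
EcoGen CBD,EcoGen Laboratories,N660,oil,24,24
Tilray,Tilray Medical,N660,oil,23,23
Delta 8 CBD—Delta 8 Pharma Grade,Delta 8 Pharma Grade,N660,oil,23,23
Hempflex Full 3000 mg,Green Care,N660,oil,23,23
CBD Calm,Kemin Industries Inc,N660,oil,22,22
Fern Valley Farms,Fern Valley Farms,N660,oil,22,22
Healist Naturals CBD,Healist Advanced Naturals LLC,N660,oil,21,21
Carolina CBD,Carolina CBD Solutions,N660,oil,20,20
CBD Emporium,CBD Emporium,N660,oil,20,20
Bisaliv CBD,Thronus Medical INC,N660,oil,19,19
Feel Good Health CBD—Feel Good Health,Feel Good Health,N660,oil,19,19
Mahara CBD Oil,Mahara CBD Group,N660,oil,19,19
DiolPure CBD,DiolPure,N660,oil,19,19
Fitosil CBD—Fitosil,Fitosil,N660,oil,18,18
Medcan Australia CBD,Medcan Australia,N660,oil,18,18
Just Hemp CBD—Just Hemp,Just Hemp,N660,oil,18,18
Nabix,Biota Biosciences,N660,oil,18,18
Elixir Organic CBD,Elixir Organic,N660,oil,18,18
Tinkun CBD,Tinkun Olam,N660,oil,17,17
Medropharm CBD,Medropharm GmbH,N660,oil,17,17
1 Pure CBD,Pure,N660,oil,16,16
Isodiolex CBD (Isodiol)—Isodiol,Isodiol,N660,oil,16,16
Clever Leaves CBD,Clever Leaves 360,N660,oil,16,16
FoliuMed CBD—FoliuMed,FoliuMed,N660,oil,15,15
Formula Swiss—Full Spectrum CBD—Formula Swiss A.G,Formula Swiss A.G,N660,oil,15,15
Spectrum Therapeutics,Spectrum Therapeutics,N660,oil,15,15
HempFlex CBD—Green Care—Green Care,Green Care,N660,oil,14,14
FitoCBD—FitoFarma—Neurogan,FitoFarma,N660,oil,13,13
Cannapresso CBD Oil—Tincture,Cannapresso CBD,N660,tincture,13,13
Panaxia CBD/THC,Panaxia Pharmaceutical Industries Ltd,N660,oil,12,12
Tegra USALINE CBD,Korasana,N660,oil,12,12
Cannabin Omega,PBG Global,N660,oil,11,11
Valens CBD,Valens CBD LLC,N660,oil,11,11
Nuvita CBD Oil,Nuvita,N660,oil,11,11
Tegra Latam Line,FoliuMed,N660,oil,11,11
Blue Ridge Hemp CBD,Blue Ridge Hemp,N660,oil,10,10
MedReleaf,MedRealef,N660,oil,9,9
Greenmed—CBD—Greenmed,Greenmed,N660,oil,9,9
CIDCAM CBD Aceite,CIDCAM Cannabis,N660,oil,8,8
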