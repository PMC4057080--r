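species,scientific_name,prev_train,prev_test,prev_dry,tp,fp,tn,fn,accuracy_main,auc_main,accuracy_dry,auc_dry
Canada Goose,Branta canadensis,0.18,0.18,0.09,92,211,457,60,67,0.71,76,0.61
Wood Duck,Aix sponsa,0.06,0.07,0.04,24,187,576,30,73,0.70,84,0.81
Gadwall,Anas strepera,0.11,0.12,0.00,82,183,534,18,75,0.89,74,0.87
American Wigeon,Anas americana,0.05,0.07,0.04,36,129,632,20,82,0.84,71,0.66
Mallard,Anas platyrhynchos,0.60,0.59,0.55,343,101,231,142,70,0.77,57,0.65
Blue-winged Teal,Anas discors,0.36,0.38,0.24,259,139,368,51,77,0.86,63,0.74
Northern Shoveler,Anas clypeata,0.17,0.18,0.09,117,189,481,30,73,0.84,68,0.81
Northern Pintail,Anas acuta,0.21,0.24,0.10,153,161,463,40,75,0.85,69,0.85
Green-winged Teal,Anas crecca,0.05,0.05,0.03,29,180,592,19,77,0.85,72,0.58
Redhead,Aythya americana,0.15,0.12,0.03,87,126,593,11,83,0.91,81,0.95
Ruddy Duck,Oxyura jamaicensis,0.13,0.11,0.06,83,115,612,7,85,0.94,83,0.92
Pied-billed Grebe,Podilymbus podiceps,0.22,0.24,0.11,166,150,474,27,78,0.90,73,0.81
Double-crested Cormorant,Phalacrocorax auritus,0.09,0.09,0.05,64,201,542,10,74,0.84,68,0.75
American Bittern,Botaurus lentiginosus,0.24,0.27,0.17,190,173,421,33,75,0.84,64,0.76
Great Blue Heron,Ardea herodias,0.07,0.06,0.04,29,180,592,19,76,0.69,88,0.67
Sora,Porzana carolina,0.28,0.27,0.16,178,154,443,42,76,0.86,63,0.71
American Coot,Fulica americana,0.28,0.29,0.15,201,117,467,32,82,0.90,72,0.86
Killdeer,Charadrius vociferus,0.88,0.92,0.86,507,27,41,242,67,0.69,69,0.59
Upland Sandpiper,Bartramia longicauda,0.49,0.48,0.53,308,128,300,81,74,0.82,81,0.84
Willet,Tringa semipalmata,0.16,0.15,0.13,111,163,532,11,79,0.91,70,0.90
Marbled Godwit,Limosa fedoa,0.19,0.18,0.24,121,166,505,28,76,0.88,75,0.90
Wilson's Snipe,Gallinago delicata,0.19,0.20,0.14,140,163,494,23,77,0.90,72,0.80
Wilson's Phalarope,Phalaropus tricolor,0.10,0.12,0.04,79,165,550,23,77,0.86,66,0.84
Franklin's Gull,Leucophaeus pipixcan,0.10,0.11,0.09,64,189,538,26,74,0.81,73,0.86
Ring-billed Gull,Larus delawarensis,0.12,0.16,0.12,103,179,510,25,75,0.84,66,0.78
Black Tern,Chlidonias niger,0.17,0.17,0.07,112,172,505,28,76,0.85,72,0.89
Sedge Wren,Cistothorus platensis,0.27,0.26,0.17,142,168,434,73,71,0.76,81,0.71
Marsh Wren,Cistothorus palustris,0.23,0.24,0.17,166,130,493,28,81,0.89,73,0.78
Common Yellowthroat,Geothlypis trichas,0.83,0.84,0.81,444,41,91,241,65,0.74,60,0.76
Song Sparrow,Melospiza melodia,0.66,0.66,0.57,425,105,172,115,73,0.78,74,0.85
Yellow-headed Blackbird,Xanthocephalus xanthocephalus,0.54,0.56,0.56,348,86,321,62,82,0.88,64,0.76
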