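species,rank,entry
Canada Goose,1,P-5yr_sd(+)
Canada Goose,2,T-sum(+)
Canada Goose,3,T-spr(-)
Canada Goose,4,T-10yr(-)
Canada Goose,5,P-10yr_sd(-)
Canada Goose,6,T-1yr(-)
Canada Goose,7,T-wint(-)
Canada Goose,8,T-5yr(-)
Canada Goose,9,W-seas(-)
Canada Goose,10,P-10yr(-)
Mallard,1,W-semi(+)
Mallard,2,W-total(+)
Mallard,3,W-pal(+)
Mallard,4,W-river(-)
Mallard,5,U-crop(-)
Mallard,6,P-10yr(-)
Mallard,7,W-temp(+)
Mallard,8,T-wint(+)
Mallard,9,T-spr(~)
Mallard,10,W-shrub(-)
Blue-winged Teal,1,W-total(+)
Blue-winged Teal,2,W-semi(+)
Blue-winged Teal,3,U-crop(-)
Blue-winged Teal,4,W-lake(+)
Blue-winged Teal,5,P-fall(+)
Blue-winged Teal,6,W-pal(+)
Blue-winged Teal,7,U-grass(+)
Blue-winged Teal,8,T-wint(+)
Blue-winged Teal,9,P-sum(+)
Blue-winged Teal,10,T-sum(-)
Northern Shoveler,1,W-semi(+)
Northern Shoveler,2,T-1yr(m)
Northern Shoveler,3,T-wint(m)
Northern Shoveler,4,W-total(+)
Northern Shoveler,5,W-lake(+)
Northern Shoveler,6,P-10yr_sd(-)
Northern Shoveler,7,T-5yr(-)
Northern Shoveler,8,U-crop(-)
Northern Shoveler,9,T-10yr(-)
Northern Shoveler,10,W-seas(-)
Northern Pintail,1,U-tree(-)
Northern Pintail,2,W-semi(+)
Northern Pintail,3,T-spr(-)
Northern Pintail,4,P-10yr(-)
Northern Pintail,5,T-1yr(-)
Northern Pintail,6,P-fall(+)
Northern Pintail,7,W-total(+)
Northern Pintail,8,T-5yr(-)
Northern Pintail,9,T-wint(-)
Northern Pintail,10,W-pal(+)
Pied-billed Grebe,1,W-lake(+)
Pied-billed Grebe,2,U-crop(-)
Pied-billed Grebe,3,U-grass(+)
Pied-billed Grebe,4,W-semi(+)
Pied-billed Grebe,5,W-seas(m)
Pied-billed Grebe,6,W-total(+)
Pied-billed Grebe,7,T-wint(+)
Pied-billed Grebe,8,P-5yr_sd(-)
Pied-billed Grebe,9,W-pal(+)
Pied-billed Grebe,10,U-devel(-)
American Bittern,1,U-grass(+)
American Bittern,2,W-semi(+)
American Bittern,3,W-total(+)
American Bittern,4,U-crop(-)
American Bittern,5,W-lake(+)
American Bittern,6,W-pal(+)
American Bittern,7,T-sum(-)
American Bittern,8,U-devel(-)
American Bittern,9,P-fall(+)
American Bittern,10,W-seas(+)
Sora,1,T-10yr_sd(+)
Sora,2,T-sum(-)
Sora,3,W-river(-)
Sora,4,W-total(+)
Sora,5,P-5yr_sd(-)
Sora,6,W-pal(+)
Sora,7,W-seas(+)
Sora,8,U-tree(-)
Sora,9,W-temp(+)
Sora,10,W-lake(+)
American Coot,1,W-semi(+)
American Coot,2,W-lake(+)
American Coot,3,W-total(+)
American Coot,4,W-pal(+)
American Coot,5,U-crop(-)
American Coot,6,T-5yr_sd(+)
American Coot,7,T-10yr_sd(+)
American Coot,8,P-spr(-)
American Coot,9,W-temp(+)
American Coot,10,W-seas(m)
Killdeer,1,P-10yr_sd(-)
Killdeer,2,T-5yr_sd(-)
Killdeer,3,U-grass(+)
Killdeer,4,U-devel(+)
Killdeer,5,T-fall(-)
Killdeer,6,W-semi(+)
Killdeer,7,T-sum(+)
Killdeer,8,U-tree(-)
Killdeer,9,T-5yr(-)
Killdeer,10,P-1yr(-)
Upland Sandpiper,1,U-grass(+)
Upland Sandpiper,2,U-tree(-)
Upland Sandpiper,3,W-seas(+)
Upland Sandpiper,4,U-crop(-)
Upland Sandpiper,5,P-10yr(-)
Upland Sandpiper,6,W-total(+)
Upland Sandpiper,7,W-pal(+)
Upland Sandpiper,8,W-semi(+)
Upland Sandpiper,9,W-temp(+)
Upland Sandpiper,10,T-wint(+)
Willet,1,P-10yr(-)
Willet,2,P-5yr(-)
Willet,3,W-total(+)
Willet,4,U-tree(-)
Willet,5,W-semi(+)
Willet,6,W-pal(+)
Willet,7,W-seas(+)
Willet,8,P-10yr_sd(-)
Willet,9,T-sum(m)
Willet,10,U-crop(-)
Marbled Godwit,1,W-lake(+)
Marbled Godwit,2,U-tree(-)
Marbled Godwit,3,W-total(+)
Marbled Godwit,4,P-10yr(-)
Marbled Godwit,5,U-crop(-)
Marbled Godwit,6,W-river(-)
Marbled Godwit,7,T-10yr(-)
Marbled Godwit,8,P-5yr(-)
Marbled Godwit,9,T-5yr(-)
Marbled Godwit,10,W-pal(+)
Wilson's Snipe,1,W-lake(+)
Wilson's Snipe,2,W-total(+)
Wilson's Snipe,3,T-10yr(-)
Wilson's Snipe,4,T-5yr(-)
Wilson's Snipe,5,P-5yr_sd(-)
Wilson's Snipe,6,W-temp(+)
Wilson's Snipe,7,T-1yr(-)
Wilson's Snipe,8,U-tree(-)
Wilson's Snipe,9,W-seas(-)
Wilson's Snipe,10,T-spr(-)
Franklin's Gull,1,W-total(+)
Franklin's Gull,2,W-lake(+)
Franklin's Gull,3,T-10yr(-)
Franklin's Gull,4,P-fall(~)
Franklin's Gull,5,P-5yr_sd(+)
Franklin's Gull,6,T-10yr_sd(-)
Franklin's Gull,7,T-spr(-)
Franklin's Gull,8,T-5yr(-)
Franklin's Gull,9,T-1yr(-)
Franklin's Gull,10,U-devel(-)
Ring-billed Gull,1,W-lake(+)
Ring-billed Gull,2,U-crop(-)
Ring-billed Gull,3,P-fall(+)
Ring-billed Gull,4,P-10yr(-)
Ring-billed Gull,5,P-spr(-)
Ring-billed Gull,6,U-grass(+)
Ring-billed Gull,7,P-5yr(-)
Ring-billed Gull,8,T-fall(-)
Ring-billed Gull,9,P-10yr(-)
Ring-billed Gull,10,P-10yr_sd(-)
Black Tern,1,U-crop(-)
Black Tern,2,W-pal(+)
Black Tern,3,W-lake(-)
Black Tern,4,W-temp(+)
Black Tern,5,W-semi(+)
Black Tern,6,T-5yr_sd(+)
Black Tern,7,W-total(+)
Black Tern,8,T-spr(-)
Black Tern,9,T-fall(m)
Black Tern,10,T-5yr(-)
Sedge Wren,1,T-sum(-)
Sedge Wren,2,W-total(+)
Sedge Wren,3,T-1yr(-)
Sedge Wren,4,T-10yr_sd(-)
Sedge Wren,5,W-lake(+)
Sedge Wren,6,T-10yr(-)
Sedge Wren,7,U-crop(-)
Sedge Wren,8,P-10yr(+)
Sedge Wren,9,P-5yr(+)
Sedge Wren,10,W-forest(+)
Marsh Wren,1,W-semi(+)
Marsh Wren,2,W-total(+)
Marsh Wren,3,W-lake(+)
Marsh Wren,4,U-grass(+)
Marsh Wren,5,W-pal(+)
Marsh Wren,6,U-crop(-)
Marsh Wren,7,T-10yr(+)
Marsh Wren,8,T-fall(+)
Marsh Wren,9,T-5yr(+)
Marsh Wren,10,W-seas(-)
Common Yellowthroat,1,W-semi(+)
Common Yellowthroat,2,U-crop(-)
Common Yellowthroat,3,W-temp(+)
Common Yellowthroat,4,W-pal(+)
Common Yellowthroat,5,W-total(+)
Common Yellowthroat,6,U-tree(+)
Common Yellowthroat,7,P-5yr_sd(-)
Common Yellowthroat,8,W-lake(+)
Common Yellowthroat,9,T-5yr(-)
Common Yellowthroat,10,W-seas(+)
Song Sparrow,1,U-grass(-)
Song Sparrow,2,U-tree(+)
Song Sparrow,3,W-semi(-)
Song Sparrow,4,U-crop(+)
Song Sparrow,5,P-sum(+)
Song Sparrow,6,P-10yr(+)
Song Sparrow,7,P-1yr(+)
Song Sparrow,8,U-devel(+)
Song Sparrow,9,T-10yr(-)
Song Sparrow,10,T-5yr(-)
Yellow-headed Blackbird,1,W-semi(+)
Yellow-headed Blackbird,2,P-10yr(-)
Yellow-headed Blackbird,3,W-pal(+)
Yellow-headed Blackbird,4,W-total(+)
Yellow-headed Blackbird,5,P-5yr(-)
Yellow-headed Blackbird,6,W-seas(+)
Yellow-headed Blackbird,7,U-crop(-)
Yellow-headed Blackbird,8,U-grass(+)
Yellow-headed Blackbird,9,P-10yr_sd(-)
Yellow-headed Blackbird,10,U-tree(-)
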