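species,cgcm,wrfc,average
Canada Goose,-76,-66,-71
Wood Duck,-70,-37,-54
Gadwall,49,-87,-19
American Wigeon,-58,-71,-65
Mallard,-30,-23,-27
Blue-winged Teal,-9,-4,-7
Northern Shoveler,-51,-62,-57
Northern Pintail,-45,-37,-41
Green-winged Teal,-46,-18,-32
Redhead,-42,-35,-39
Ruddy Duck,-30,-31,-31
Pied-billed Grebe,-40,-18,-29
Double-crested Cormorant,-11,-20,-16
American Bittern,-42,-42,-42
Great Blue Heron,-72,-82,-77
Sora,-94,-98,-96
American Coot,-38,-38,-38
Killdeer,5,0,3
Upland Sandpiper,8,7,8
Willet,-43,-58,-51
Marbled Godwit,-53,-61,-57
Wilson's Snipe,-99,-100,-100
Wilson's Phalarope,-42,-60,-51
Franklin's Gull,-93,-98,-96
Ring-billed Gull,-39,-83,-61
Black Tern,-67,-64,-66
Sedge Wren,-71,-60,-66
Marsh Wren,-40,-42,-41
Common Yellowthroat,-26,-35,-31
Song Sparrow,-38,-41,-40
Yellow-headed Blackbird,-24,-25,-25
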