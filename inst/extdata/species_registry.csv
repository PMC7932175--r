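scientific_name,common_name
Aluterus schoepfii,orange filefish
Balistes capriscus,gray triggerfish
Calamus proridens,littlehead porgy
Caranx crysos,blue runner
Carcharhinus obscurus,dusky shark
Centropristis ocyurus,bank seabass
Chaetodon aya,bank butterflyfish
Chaetodon ocellatus,spotfin butterflyfish
Chromis enchrysura,yellowtail reeffish
Chromis scotti,purple reeffish
Diplectrum formosum,sand perch
Epinephelus itajara,goliath grouper
Epinephelus morio,red grouper
Equetus lanceolatus,jackknife fish
Pareques umbrosus,cubbyu
Haemulon aurolineatum,tomtate
Halichoeres bivittatus,slippery dick
Halichoeres poeyi,blackear wrasse
Holacanthus bermudensis,blue angelfish
Lactophrys quadricornis,scrawled cowfish
Lutjanus campechanus,red snapper
Lutjanus griseus,gray snapper
Lutjanus synagris,lane snapper
Mycteroperca microlepis,gag
Mycteroperca phenax,scamp
Ogocephalus radiatus,polkadot batfish
Pagrus pagrus,red porgy
Pristigenys alta,short bigeye
Ptereleotris calliura,blue dartfish
Pterois volitans,red lionfish
Raja texana,roundel skate
Rhinobatos lentiginosus,Atlantic guitarfish
Rhomboplites aurorubens,vermilion snapper
Rypticus maculatus,whitespotted soapfish
Seriola dumerili,greater amberjack
Seriola rivoliana,almaco jack
Sphoeroides spengleri,bandtail puffer
Stegastes leucostictus,beaugregory
Synodus intermedius,sand diver
Xyrichtys novacula,pearly razorfish
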