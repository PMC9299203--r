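"species_id","site_id","site_name","lat","lon","management_area_id"
"Gigantopelta chessoia","E2","East Scotia Ridge E2",-56.089,-30.317,"SGSSI_MPA"
"Gigantopelta chessoia","E9","East Scotia Ridge E9",-60.046,-29.984,"ANTARCTIC_TREATY"
"Dracogyra subfusca","longqi","Longqi vent field, Southwest Indian Ridge",-37.78,49.65,"ISA_COMRA_SWIR"
"Alviniconcha boucheti","manus","Manus Basin",-3.73,151.67,"EEZ_PNG"
"Alviniconcha boucheti","nfiji","North Fiji Basin",-16.99,173.92,"EEZ_FIJI"
"Alviniconcha boucheti","abe","ABE, Lau Basin",-20.76,-176.19,"EEZ_TONGA"
"Alviniconcha boucheti","mariner","Mariner, Lau Basin",-22.18,-176.57,"EEZ_TONGA"
"Bathymodiolus manusensis","pacmanus","PACMANUS",-3.73,151.67,"EEZ_PNG"
"Bathymodiolus manusensis","desmos","DESMOS",-3.693,151.858,"EEZ_PNG"
"Bathymodiolus manusensis","susu","SuSu Knolls",-3.8,152.1,"EEZ_PNG"
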