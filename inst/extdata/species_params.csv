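name,common_name,route,natal_lat,natal_lon,goal_lat,goal_lon,coords_canonical,goal_radius_km,depart_day,depart_sd,max_arrival_day,distance_gc_km,distance_lox_km,heading_gc_deg,heading_lox_deg,flight_speed_ms,step_km,consecutive_steps,stopover_mean_d,stopover_sd_d,travel_speed_kmd,n_min,n_max,beta_adj,diel,notes
monarch,Monarch butterfly,Quebec-Mexico,45.5,-73.6,19.6,-100.3,synthetic,100,227,14,347,3290,3300,219,213,3.0,85,5,3,1,55,36.9,77,0.18,day,representative coordinates (region names only in source table)
ring_ouzel,Ring ouzel,Scotland-N Africa,56.9,-4.2,33.0,-5.0,synthetic,250,243,7,333,2610,2610,181,179,11.5,330,10,15,5,130,7.1,42,0.26,night,representative coordinates
common_rosefinch,Common rosefinch,Bulgaria-NW India,42.7,25.5,28.0,73.0,synthetic,400,219,7,333,5110,5170,96,123,12.5,360,5,5,2,400,13.1,44,0.28,night,representative coordinates
marsh_warbler,Marsh warbler,Finland-Kenya,61.0,25.0,-1.0,37.0,synthetic,500,244,7,366,6720,6730,168,173,11.5,330,5,5,2,165,18.8,48,0.32,night,representative coordinates
kirtlands_warbler,Kirtland's warbler,Michigan-Bahamas,44.7,-84.7,24.7,-78.0,synthetic,300,279,7,339,2370,2370,157,160,10.0,290,5,5,2,145,7.2,33,0.34,night,representative coordinates
nathusius_bat,Nathusius bat,Latvia-Spain,56.5,21.0,42.8,2.8,synthetic,300,227,14,317,2040,2050,233,224,7.5,160,3,5,2,60,10.8,36,0.48,night,representative coordinates
willow_warbler,Willow warbler,Siberia-Zambia,67.0,160.0,-13.0,28.0,synthetic,1000,244,7,366,13200,14600,311,233,10.5,300,5,2,2,215,40.2,87,0.48,night,representative coordinates
grey_cheeked_thrush,Grey-cheeked thrush,Yukon-Colombia,64.0,-139.0,5.0,-74.0,synthetic,1000,253,7,372,9080,9300,108,141,11.5,330,5,5,2,165,24.4,63,0.54,night,representative coordinates
hoopoe,Eurasian hoopoe,Switzerland-W Africa,46.2,7.0,14.0,-5.0,synthetic,800,222,7,282,3370,3380,204,200,12.0,345,5,5,2,170,7.4,33,0.65,night,representative coordinates
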