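level,category,protection,regime,area_km2,n_areas
national,fauna_flora_sanctuary,dedicated,public,231.17,4
national,flora_sanctuary,dedicated,public,100.86,2
national,national_forest_protection_reserve,mixed,private,1974.69,39
national,national_park,dedicated,public,21290.29,22
national,natural_unique_area,dedicated,public,2.98,1
regional,regional_forest_protection_reserve,mixed,private,1126.98,52
regional,integrated_management_district,mixed,private,3169.81,53
regional,regional_natural_park,mixed,private,5022.62,37
regional,soil_conservation_district,mixed,private,236.63,6
local,civil_society_reserve,mixed,private,114.63,199
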