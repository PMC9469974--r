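name,level,area_km2
el_cocuy,national,2917.92
paramillo,national,2806.59
sumapaz,national,2144.15
cordillera_de_los_picachos,national,1918.87
farallones_de_cali,national,1658.95
nevado_del_huila,national,1586.69
las_hermosas,national,1192.72
miraflores_picachos,regional,1064.28
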