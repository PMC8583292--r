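ecosystem,unit,natural,semi,degraded,total
forest,km2,63651.34,2115.27,6124.23,71890.84
grassland,km2,7080.05,12790.72,12486.37,32357.14
cave,count,15,315,9,339
lake,km2,410.95,1521.41,315.91,2248.28
river,km,16320.52,44508.82,2238.82,84068.17
coastal,km2,42.5,1362.32,169.17,1574
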