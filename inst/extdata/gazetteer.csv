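city,country,lat,lng,pop,capital
Boston,USA,42.36,-71.06,692600,0
New York,USA,40.71,-74.01,8336817,0
Los Angeles,USA,34.05,-118.24,3979576,0
Chicago,USA,41.88,-87.63,2693976,0
Houston,USA,29.76,-95.37,2320268,0
Philadelphia,USA,39.95,-75.17,1584064,0
Seattle,USA,47.61,-122.33,753675,0
Baltimore,USA,39.29,-76.61,593490,0
San Francisco,USA,37.77,-122.42,881549,0
Stanford,USA,37.43,-122.17,13809,0
Ann Arbor,USA,42.28,-83.74,119980,0
Atlanta,USA,33.75,-84.39,506811,0
Durham,USA,35.99,-78.90,278993,0
St Louis,USA,38.63,-90.20,300576,0
Pittsburgh,USA,40.44,-79.99,300286,0
Rochester,USA,44.02,-92.47,118935,0
Cleveland,USA,41.50,-81.69,381009,0
Dallas,USA,32.78,-96.80,1343573,0
Miami,USA,25.76,-80.19,467963,0
Denver,USA,39.74,-104.99,727211,0
Nashville,USA,36.16,-86.78,670820,0
Minneapolis,USA,44.98,-93.27,429606,0
Washington,USA,38.91,-77.04,705749,1
New Haven,USA,41.31,-72.92,130250,0
Bethesda,USA,38.98,-77.10,63374,0
Portland,USA,45.52,-122.68,654741,0
San Diego,USA,32.72,-117.16,1423851,0
Aurora,USA,39.73,-104.83,379289,0
London,UK,51.51,-0.13,8982000,1
Oxford,UK,51.75,-1.26,152450,0
Cambridge,UK,52.21,0.12,125758,0
Edinburgh,UK,55.95,-3.19,524930,0
Glasgow,UK,55.86,-4.25,633120,0
Manchester,UK,53.48,-2.24,553230,0
Birmingham,UK,52.49,-1.89,1141816,0
Leeds,UK,53.80,-1.55,789194,0
Bristol,UK,51.45,-2.59,463400,0
Liverpool,UK,53.41,-2.98,498042,0
Newcastle,UK,54.98,-1.61,300196,0
Southampton,UK,50.91,-1.40,253651,0
Cardiff,UK,51.48,-3.18,364248,0
Belfast,UK,54.60,-5.93,343542,0
Toronto,Canada,43.65,-79.38,2731571,0
Montreal,Canada,45.50,-73.57,1704694,0
Vancouver,Canada,49.28,-123.12,631486,0
Ottawa,Canada,45.42,-75.70,934243,1
Hamilton,Canada,43.26,-79.87,536917,0
Edmonton,Canada,53.55,-113.49,932546,0
Calgary,Canada,51.05,-114.07,1239220,0
London,Canada,42.98,-81.25,383822,0
Quebec,Canada,46.81,-71.21,531902,0
Winnipeg,Canada,49.90,-97.14,705244,0
Paris,France,48.86,2.35,2148271,1
Lyon,France,45.76,4.84,515695,0
Marseille,France,43.30,5.37,861635,0
Toulouse,France,43.60,1.44,479553,0
Bordeaux,France,44.84,-0.58,254436,0
Lille,France,50.63,3.06,232741,0
Montpellier,France,43.61,3.88,285121,0
Strasbourg,France,48.57,7.75,280966,0
Nantes,France,47.22,-1.55,309346,0
Berlin,Germany,52.52,13.41,3644826,1
Munich,Germany,48.14,11.58,1471508,0
Hamburg,Germany,53.55,9.99,1841179,0
Heidelberg,Germany,49.40,8.67,160355,0
Frankfurt,Germany,50.11,8.68,753056,0
Cologne,Germany,50.94,6.96,1085664,0
Tubingen,Germany,48.52,9.06,90546,0
Dresden,Germany,51.05,13.74,554649,0
Leipzig,Germany,51.34,12.37,587857,0
Essen,Germany,51.46,7.01,583109,0
Amsterdam,Netherlands,52.37,4.90,872680,1
Rotterdam,Netherlands,51.92,4.48,651446,0
Utrecht,Netherlands,52.09,5.12,357597,0
Leiden,Netherlands,52.16,4.49,124899,0
Groningen,Netherlands,53.22,6.57,232826,0
Nijmegen,Netherlands,51.84,5.85,177659,0
Maastricht,Netherlands,50.85,5.69,121565,0
Sydney,Australia,-33.87,151.21,5312163,0
Melbourne,Australia,-37.81,144.96,5078193,0
Brisbane,Australia,-27.47,153.03,2514184,0
Perth,Australia,-31.95,115.86,2085973,0
Adelaide,Australia,-34.93,138.60,1345777,0
Canberra,Australia,-35.28,149.13,426704,1
Newcastle,Australia,-32.93,151.78,322278,0
Beijing,China,39.90,116.41,21542000,1
Shanghai,China,31.23,121.47,24281400,0
Guangzhou,China,23.13,113.26,15300000,0
Shenzhen,China,22.54,114.06,13438800,0
Wuhan,China,30.59,114.31,11081000,0
Chengdu,China,30.57,104.07,16330000,0
Nanjing,China,32.06,118.80,8505500,0
Hangzhou,China,30.27,120.15,10360000,0
Xian,China,34.34,108.94,12952900,0
Hong Kong,China,22.32,114.17,7482500,0
Zurich,Switzerland,47.37,8.54,415367,0
Geneva,Switzerland,46.20,6.14,201818,0
Basel,Switzerland,47.56,7.59,177595,0
Bern,Switzerland,46.95,7.45,133883,1
Lausanne,Switzerland,46.52,6.63,139111,0
Stockholm,Sweden,59.33,18.07,975551,1
Gothenburg,Sweden,57.71,11.97,579281,0
Malmo,Sweden,55.60,13.00,344166,0
Uppsala,Sweden,59.86,17.64,177074,0
Lund,Sweden,55.70,13.19,94393,0
Copenhagen,Denmark,55.68,12.57,632340,1
Aarhus,Denmark,56.16,10.20,349983,0
Odense,Denmark,55.40,10.40,180760,0
Aalborg,Denmark,57.05,9.92,217075,0
Rome,Italy,41.90,12.50,2872800,1
Milan,Italy,45.46,9.19,1396059,0
Naples,Italy,40.85,14.27,959470,0
Turin,Italy,45.07,7.69,870952,0
Bologna,Italy,44.49,11.34,390636,0
Florence,Italy,43.77,11.26,382258,0
Padua,Italy,45.41,11.88,214198,0
Tokyo,Japan,35.68,139.69,13929286,1
Osaka,Japan,34.69,135.50,2691185,0
Kyoto,Japan,35.01,135.77,1474570,0
Yokohama,Japan,35.44,139.64,3748781,0
Nagoya,Japan,35.18,136.91,2295638,0
Fukuoka,Japan,33.59,130.40,1603043,0
Sendai,Japan,38.27,140.87,1089372,0
Madrid,Spain,40.42,-3.70,3223334,1
Barcelona,Spain,41.39,2.17,1620343,0
Valencia,Spain,39.47,-0.38,791413,0
Seville,Spain,37.39,-5.98,688711,0
Granada,Spain,37.18,-3.60,232208,0
Brussels,Belgium,50.85,4.35,1208542,1
Antwerp,Belgium,51.22,4.40,523248,0
Ghent,Belgium,51.05,3.72,262219,0
Leuven,Belgium,50.88,4.70,101396,0
Liege,Belgium,50.63,5.57,197355,0
Oslo,Norway,59.91,10.75,693494,1
Bergen,Norway,60.39,5.32,283929,0
Trondheim,Norway,63.43,10.40,205163,0
Tromso,Norway,69.65,18.96,76974,0
Cape Town,South Africa,-33.92,18.42,433688,0
Johannesburg,South Africa,-26.20,28.05,957441,0
Durban,South Africa,-29.86,31.02,595061,0
Pretoria,South Africa,-25.75,28.19,741651,1
Stellenbosch,South Africa,-33.93,18.86,155733,0
Auckland,New Zealand,-36.85,174.76,1657200,0
Wellington,New Zealand,-41.29,174.78,212700,1
Christchurch,New Zealand,-43.53,172.64,377200,0
Dunedin,New Zealand,-45.87,170.50,126255,0
Jerusalem,Israel,31.77,35.21,919438,1
Tel Aviv,Israel,32.09,34.78,460613,0
Haifa,Israel,32.79,34.99,285316,0
Rehovot,Israel,31.89,34.81,132671,0
Sao Paulo,Brazil,-23.55,-46.63,12252023,0
Rio de Janeiro,Brazil,-22.91,-43.17,6718903,0
Brasilia,Brazil,-15.78,-47.93,3015268,1
Belo Horizonte,Brazil,-19.92,-43.94,2512070,0
Salvador,Brazil,-12.97,-38.50,2872347,0
Helsinki,Finland,60.17,24.94,653835,1
Turku,Finland,60.45,22.27,192962,0
Tampere,Finland,61.50,23.76,238140,0
Oulu,Finland,65.01,25.47,205489,0
Kuopio,Finland,62.89,27.68,119282,0
Vienna,Austria,48.21,16.37,1897491,1
Graz,Austria,47.07,15.44,291007,0
Innsbruck,Austria,47.27,11.40,132493,0
Salzburg,Austria,47.81,13.06,155031,0
Seoul,South Korea,37.57,126.98,9733509,1
Busan,South Korea,35.18,129.08,3448737,0
Daegu,South Korea,35.87,128.60,2461769,0
Incheon,South Korea,37.46,126.71,2957026,0
New Delhi,India,28.61,77.21,257803,1
Mumbai,India,19.08,72.88,12442373,0
Bangalore,India,12.97,77.59,8443675,0
Chennai,India,13.08,80.27,7088000,0
Kolkata,India,22.57,88.36,4496694,0
Hyderabad,India,17.39,78.49,6809970,0
Vellore,India,12.92,79.13,185803,0
Singapore,Singapore,1.35,103.82,5703600,1
Dublin,Ireland,53.35,-6.26,554554,1
Cork,Ireland,51.90,-8.47,210000,0
Galway,Ireland,53.27,-9.05,79934,0
Bangkok,Thailand,13.76,100.50,8305218,1
Chiang Mai,Thailand,18.79,98.98,127240,0
Khon Kaen,Thailand,16.44,102.84,115928,0
Nairobi,Kenya,-1.29,36.82,4397073,1
Kisumu,Kenya,-0.09,34.77,409928,0
Kilifi,Kenya,-3.63,39.85,122899,0
Mombasa,Kenya,-4.04,39.66,1208333,0
Athens,Greece,37.98,23.73,664046,1
Thessaloniki,Greece,40.64,22.94,325182,0
Ioannina,Greece,39.67,20.85,65574,0
Heraklion,Greece,35.34,25.13,140730,0
Karachi,Pakistan,24.86,67.01,14910352,0
Lahore,Pakistan,31.55,74.34,11126285,0
Islamabad,Pakistan,33.68,73.05,1014825,1
Rawalpindi,Pakistan,33.56,73.02,2098231,0
Riyadh,Saudi Arabia,24.71,46.68,7676654,1
Jeddah,Saudi Arabia,21.49,39.19,4697000,0
Dammam,Saudi Arabia,26.43,50.10,1252523,0
Dhaka,Bangladesh,23.81,90.41,8906039,1
Chittagong,Bangladesh,22.36,91.78,2581643,0
Matlab,Bangladesh,23.35,90.71,44000,0
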