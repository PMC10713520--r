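country,population
USA,328239523
UK,66834405
Canada,37589262
France,67248926
Germany,83092962
Netherlands,17332850
Australia,25365745
China,1397715000
Switzerland,8574832
Sweden,10278887
Denmark,5814422
Italy,59729081
Japan,126261000
Spain,47134837
Belgium,11488980
Norway,5347896
South Africa,58558270
New Zealand,4979200
Israel,9054000
Brazil,211049527
Finland,5521606
Austria,8879920
South Korea,51709098
India,1366417754
Singapore,5703569
Ireland,4934340
Thailand,69625582
Kenya,52573973
Greece,10716322
Pakistan,216565318
Saudi Arabia,34268528
Bangladesh,163046161
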