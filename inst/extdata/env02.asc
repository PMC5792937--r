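ncols 12
nrows 12
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.8943536728 0.8174693016 0.6540443394 0.4722869392 0.3619509811 0.3487821233 0.3838136049 0.4105068980 0.4239203872 0.4515153154 0.4923837660 0.5221793254
0.8180120817 0.7610805519 0.6240890301 0.4573410476 0.3322447073 0.2838949169 0.3002460563 0.3517991109 0.4191411243 0.4917683224 0.5484369426 0.5733647777
0.7797826452 0.7182098938 0.5841328915 0.4185275460 0.2786621456 0.2036511544 0.2082531918 0.2844111626 0.4006209680 0.5135264624 0.5840863764 0.6038394543
0.7894529976 0.6965900373 0.5411088858 0.3624974094 0.2076419872 0.1134384478 0.1095962052 0.2034513771 0.3572477228 0.5047845334 0.5928938510 0.6157447699
0.79656847078 0.67166802903 0.49667232702 0.30929889260 0.14626170190 0.03943931321 0.02730443350 0.12957994957 0.30879425951 0.48659699797 0.59975208443 0.63967904268
0.75219725268 0.62368358476 0.45788543558 0.28418954963 0.12812507985 0.01821350258 0.00000000000 0.10327468277 0.29567808797 0.49745701949 0.64171044667 0.71402252901
0.67863398428 0.57627021040 0.44552986994 0.30406278374 0.16912741917 0.06943197252 0.05383845997 0.15544944638 0.34769495091 0.55920857505 0.72871223321 0.83764263440
0.6479024265 0.5810786816 0.4869392970 0.3760196278 0.2654876415 0.1873064101 0.1858589171 0.2862517232 0.4636353323 0.6608423174 0.8312778931 0.9588128358
0.6889969959 0.6565994155 0.5878132012 0.4937055615 0.4006309208 0.3461886334 0.3632749133 0.4592531288 0.6051419085 0.7582257145 0.8915540513 1.0000000000
0.7518152872 0.7635983069 0.7208094247 0.6379721433 0.5549807353 0.5163454511 0.5423013255 0.6211760113 0.7177617095 0.8010458665 0.8631630748 0.9156059772
0.7674305315 0.8464706903 0.8486260274 0.7886090169 0.7173264625 0.6848990701 0.7024182420 0.7464657572 0.7800992755 0.7824692310 0.7604944777 0.7417289386
0.7190871091 0.8813135854 0.9468342100 0.9258379679 0.8739299007 0.8430620655 0.8393115280 0.8373959043 0.8062615500 0.7357167588 0.6423811228 0.5644093989
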