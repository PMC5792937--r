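ncols 12
nrows 12
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
-9.999000000e+03 3.980499805e-01 3.751425564e-01 2.964955701e-01 1.727417965e-01 5.327632438e-02 0.000000000e+00 3.914689640e-02 1.450863561e-01 2.687767103e-01 3.771953613e-01 4.530909534e-01
0.4456873710 0.4655118969 0.4606427004 0.4204272388 0.3566156348 0.2951521043 0.2630075216 0.2690696798 0.3009398812 0.3400190346 0.3763363344 0.4031012077
0.4569110382 0.5019643509 0.5266674539 0.5291629635 0.5197855657 0.5054674017 0.4856594449 0.4566584905 0.4200769384 0.3874627444 0.3717932517 0.3738991790
0.4389164100 0.5107495385 0.5664306511 0.6050306908 0.6338461472 0.6496610307 0.6362551433 0.5817769336 0.4973304614 0.4175180601 0.3748981494 0.3754470850
0.4324699884 0.5165587074 0.5890351196 0.6463052793 0.6943526634 0.7290244118 0.7276832531 0.6702860145 0.5681022842 0.4671836100 0.4139755211 0.4192504096
0.4811559980 0.5479667327 0.6077434210 0.6580222243 0.7083808766 0.7591068631 0.7841671490 0.7514820176 0.6620663933 0.5609154662 0.5011428764 0.4996797449
0.5929016639 0.6088378091 0.6231323454 0.6425337982 0.6836979913 0.7499911266 0.8103930324 0.8188249898 0.7606584886 0.6708936017 0.6021217912 0.5783493198
0.7353091987 0.6759327784 0.6246690785 0.6029294050 0.6311639302 0.7082420015 0.7966643235 0.8413308387 0.8148273316 0.7385357950 0.6585072993 0.6047054717
0.8600509846 0.7187189248 0.6026497793 0.5461174069 0.5636543943 0.6411552011 0.7375449998 0.8003358147 0.7974712282 0.7353505353 0.6473618344 0.5658475250
0.9393618983 0.7249828949 0.5578093821 0.4784973832 0.4870518612 0.5535368844 0.6402199745 0.7087585507 0.7285298625 0.6873855529 0.5986833139 0.4928843956
0.9775941804 0.7052169684 0.4996044516 0.4026473749 0.3991295959 0.4479395556 0.5212509917 0.5990618790 0.6513464979 0.6415990145 0.5569909388 0.4239450125
1.0000000000 0.6833615711 0.4448342900 0.3266991824 0.3051201374 0.3358695605 0.4032171158 0.5012423037 0.5948878523 0.6198393080 0.5363246233 -9999.0000000000
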