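"species","longitude","latitude"
"sp01",4.5,11.5
"sp01",10.5,11.5
"sp01",9.5,6.5
"sp01",8.5,9.5
"sp01",3.5,6.5
"sp01",6.5,10.5
"sp02",2.5,11.5
"sp02",11.5,6.5
"sp02",2.5,9.5
"sp02",5.5,9.5
"sp02",3.5,3.5
"sp02",4.5,3.5
"sp03",3.5,3.5
"sp03",3.5,9.5
"sp03",9.5,8.5
"sp03",4.5,10.5
"sp03",10.5,6.5
"sp03",2.5,7.5
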