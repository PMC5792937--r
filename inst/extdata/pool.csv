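"species","longitude","latitude"
"pool",1.5,0.5
"pool",5.5,3.5
"pool",0.5,6.5
"pool",7.5,0.5
"pool",11.5,6.5
"pool",2.5,7.5
"pool",4.5,10.5
"pool",5.5,8.5
"pool",9.5,1.5
"pool",6.5,11.5
"pool",8.5,1.5
"pool",8.5,7.5
"pool",2.5,0.5
"pool",0.5,8.5
"pool",3.5,11.5
"pool",3.5,1.5
"pool",2.5,2.5
"pool",0.5,2.5
"pool",9.5,0.5
"pool",3.5,9.5
"pool",6.5,7.5
"pool",7.5,5.5
"pool",1.5,5.5
"pool",8.5,4.5
"pool",11.5,3.5
"pool",11.5,10.5
"pool",4.5,5.5
"pool",3.5,2.5
"pool",8.5,8.5
"pool",1.5,10.5
"pool",11.5,8.5
"pool",2.5,11.5
"pool",8.5,6.5
"pool",1.5,2.5
"pool",9.5,10.5
"pool",6.5,4.5
"pool",1.5,3.5
"pool",7.5,9.5
"pool",6.5,0.5
"pool",5.5,1.5
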