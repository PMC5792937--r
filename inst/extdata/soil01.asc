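ncols 12
nrows 12
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
1 1 1 1 1 1 1 1 1 1 1 1
1 1 1 1 1 1 1 1 2 2 1 1
1 1 1 1 2 2 2 3 3 2 1 1
2 2 2 2 3 3 4 4 4 2 2 1
3 2 2 3 3 4 4 4 4 3 1 1
3 3 3 3 4 4 4 4 4 3 1 1
3 3 3 3 4 4 4 4 4 2 1 1
4 4 4 3 3 4 4 4 3 2 2 1
4 4 3 3 3 3 3 3 3 2 2 2
4 4 3 2 2 3 3 3 2 3 3 4
4 4 2 2 2 2 3 2 2 3 4 4
4 3 2 2 2 2 2 2 2 4 4 4
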