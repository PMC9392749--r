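   SW   perc perc perc  query     position in query    matching  repeat         position in repeat
score   div. del. ins.  sequence  begin  end   (left)  repeat    class/family   begin  end (left)  ID

 1207   10.1  0.3  0.2  chr8   128000001 128000200 (18363647)  +  LTR66    LTR/ERVL       1  200  (400)  7
  981   10.4  0.1  0.2  chr8   128002401 128002600 (18361247)  +  LTR66    LTR/ERVL     201  400  (200)  7
 2316    8.2  0.4  0.1  chr8   128010001 128010300 (18353547)  +  AluSx1   SINE/Alu       1  300    (0)  8
 1742   18.5  1.2  0.9  chr8   128012001 128012400 (18351447)  C  LTR33    LTR/ERVL       1  400    (0)  9
 1318   21.0  2.1  1.4  chr8   128014001 128014350 (18349497)  +  L2b      LINE/L2        1  350    (0)  10
 1411   16.2  0.8  0.6  chr8   128016001 128016300 (18347547)  +  MLT1F1   LTR/ERVL-MaLR  1  300    (0)  11
 1650   12.0  0.5  0.3  chr2     5000001   5000400 (237000000)  +  LTR43    LTR/ERVL       1  400    (0)  21
 4105   15.3  1.1  0.8  chr2     5000901   5002900 (236997500)  +  LTR43-int LTR/ERVL      1 2000    (0)  22
 1633   12.4  0.4  0.5  chr2     5003401   5003800 (236996600)  +  LTR43    LTR/ERVL       1  400    (0)  23
 2280    3.0  0.1  0.1  chr2     6000001   6000310 (235999690)  +  AluY     SINE/Alu       1  310    (0)  24
 1999    9.7  0.3  0.4  chr2     7000001   7000299 (234999701)  C  AluSx4   SINE/Alu       1  299    (0)  25
 1456   19.8  1.6  1.2  chr2     8000001   8000420 (233999580)  +  MLT1A0   LTR/ERVL-MaLR  1  420    (0)  26
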