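pile_id,distances_m,day,type,localization,zones
A1,2.5;17.5;32.5,20,hot,In the center,center
A1,2.5;32.5,28,hot,In the center,center
A1,32.5,41,hot,In the top left corner,top;left
A2,2.5,25,hot,In the center of pile,center
A2,2.5,32,hot,In the top left corner,top;left
A2,17.5,47,hot,In the top left corner,top;left
B1,17.5,9,hot,In the center of pile,center
B1,2.5;17.5;32.5;47.5,16,hot,In the center and left side,center;left
B1,2.5;17.5;32.5;47.5,22,hot,In the center and left side,center;left
B1,2.5;17.5;32.5;47.5,31,hot,In the center and left side,center;left
B1,2.5;17.5;32.5;47.5,41,hot,In the center and left side,center;left
B1,17.5,57,hot,In the left bottom corner,bottom;left
B2,2.5;32.5;47.5,8,hot,In the center and left side,center;left
B2,32.5,16,hot,In the left bottom corner,bottom;left
B2,17.5;32.5;47.5,24,hot,In the center and right side,center;right
B2,32.5,43,hot,Right down corner,bottom;right
C1,32.5,28,hot,In the center,center
C2,17.5,9,hot,On the right side,right
C2,32.5,21,hot,On the left side,left
C2,17.5,35,hot,On the left and right corner,left;right
A1,2.5;17.5;32.5,20,cold,In the left side in the bottom,left;bottom
A1,2.5;32.5,28,cold,In the bottom,bottom
A2,2.5;17.5,17,cold,In the bottom,bottom
A2,2.5;17.5;32.5,25,cold,In the bottom,bottom
A2,2.5;17.5,38,cold,In the bottom,bottom
A2,2.5;17.5;32.5;47.5,57,cold,In the bottom,bottom
B1,32.5;47.5,1,cold,In the bottom and in the center,bottom;center
B2,2.5;17.5;32.5;47.5,1,cold,In the bottom,bottom
B2,2.5,43,cold,In the bottom and in the center,bottom;center
C1,2.5;17.5,28,cold,"left side, near to sidewalls and in the bottom",left;near-sidewall;bottom
C1,2.5;32.5;47.5,35,cold,"left side, near to sidewalls",left;near-sidewall
C1,2.5;32.5;47.5,42,cold,"Left and right side, near to sidewalls",left;right;near-sidewall
C2,2.5;17.5;32.5;47.5,1,cold,In the bottom,bottom
C2,32.5;47.5,28,cold,In the bottom,bottom
C2,2.5;32.5;47.5,35,cold,"In the bottom, left side, near to sidewalls",bottom;left;near-sidewall
C2,2.5;32.5;47.5,42,cold,"In the bottom, left side, near to sidewalls",bottom;left;near-sidewall
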