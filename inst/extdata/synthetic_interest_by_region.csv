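Country,itch,scar
US,77,23
GB,75,25
DE,100,0
FR,60,40
IT,100,0
ES,0,100
PL,64,36
NL,100,0
BE,61,39
SE,100,0
NO,64,36
FI,69,31
DK,69,31
IE,,
PT,80,20
GR,54,46
CZ,73,27
SK,83,17
HU,68,32
RO,72,28
BG,72,28
HR,73,27
SI,67,33
AT,,
CH,69,31
RU,77,23
UA,47,53
TR,,
IL,58,42
SA,71,29
AE,57,43
EG,71,29
MA,62,38
ZA,46,54
NG,,
KE,48,52
IN,57,43
PK,55,45
BD,46,54
LK,90,10
TH,77,23
VN,70,30
ID,54,46
MY,60,40
PH,0,100
SG,62,38
JP,54,46
KR,58,42
CN,100,0
TW,73,27
HK,70,30
AU,60,40
NZ,82,18
BR,,
AR,75,25
CL,87,13
CO,100,0
PE,70,30
MX,85,15
CA,100,0
VE,64,36
EC,70,30
UY,58,42
BO,80,20
CR,65,35
PA,73,27
DO,,
JM,77,23
TT,70,30
IS,59,41
MT,81,19
LU,0,100
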