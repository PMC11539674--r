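code,accession_no,local_name,country
PR1,"PI 206,043",,Puerto Rico
BR1,"PI 118,279",Pepino verde comprido,Brazil
CA1,"PI 229,808",55-64,Canada
CA2,Ames 3949,"G 18,172",Canada
MU1,"PI 525,075",Concombre blanc,Mauritius
ET1,"PI 193,497",Elsgruber Znainer,Ethiopia
EG1,"PI 525,150",8,Egypt
EG2,"PI 525,155",55,Egypt
EG3,"PI 288,237",Balady,Egypt
EG4,"PI 188,749",Baladi,Egypt
HU1,"PI 288,995",Nemet Kigyo,Hungary
HU2,"PI 507,876","2,701,000",Hungary
ES1,"PI 512,641",V-C-93,Spain
ES2,"Ames 13,356",Medio largo verde,Spain
ES3,"PI 261,608",Pepino medio largo verde,Spain
BA1,"PI 357,854",Vodjanska,Bosnia
MK1,"PI 357,832",Kusa,Macedonia
MK2,"PI 368,560",Vratnicka,Macedonia
MK3,"PI 357,834",Zelena,Macedonia
PL1,"PI 285,603",Delikates,Poland
MD1,"PI 263,080",Tiraspolski rannii,Moldova
GR1,"PI 212,059",Kalivia,Greece
UA1,"PI 263,078",Nezhinsky 12,Ukraine
RS1,"PI 379,280",Bela,Serbia
AF1,"PI 212,599","13,112",Afghanistan
CN1,"PI 618,898",Xiao Ba Ca,China
CN2,"PI 391,571",Nanking thorny,China
CN3,"PI 103,049",Kuai Huang Kua,China
IN1,"PI 605,987",USM 410,India
IN2,"PI 217,644","13,765",India
IN3,"PI 197,085","11,762",India
IN4,"PI 164,284",8920,India
IN5,"PI 271,337",1744,India
JP1,"PI 227,210",Aibai,Japan
IQ1,"PI 177,364",9884,Iraq
KZ1,"Ames 19,038","Ames 19,038",Kazakhstan
RU1,"PI 392,292",Iziascnyj,Russia
LB1,"PI 218,199",Chebab,Lebanon
OM1,"PI 532,162",Ashebe,Oman
PH1,"PI 188,807",Pepino,Philippines
SY1,"PI 181,752",9748,Syria
KR1,"PI 281,448",9,South Korea
NP1,"PI 427,230",,Nepal
TR1,"PI 338,236",Ames 1208,Türkiye
TR2,"PI 178,887",9677,Türkiye
TR3,"PI 169,398",Dikenli,Türkiye
TR4,"PI 171,601",Rus Cinsi,Türkiye
TR5,"PI 176,524",9480,Türkiye
IR1,"PI 222,244",1424,Iran
IR2,"PI 137,844",Khiyar,Iran
IR3,"PI 137,845",Khiyar,Iran
PK1,"PI 163,216",8307,Pakistan
PK2,"PI 269,482",650,Pakistan
PK3,"PI 330,628",Kshira,Pakistan
TH1,"PI 249,562",Teang-rhan,Thailand
MM1,"PI 200,818",94,Myanmar
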