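marker,code,h,na,i,pic,band_sizes
EC 11,A,0.98,4,1.28,0.64,115;199;240;260;350
EC 12,B,0.58,5,1.27,0.60,156;220;250;400;900
EC 13,C,0.85,6,0.97,0.46,244;260;265;310;350;355
EC 15,D,0.75,5,1.07,0.52,267;270;300;310;320
EC 17,E,0.96,9,1.73,0.74,300;310;340;350;370;380;400;425;510
EC 18,F,0.13,3,0.27,0.12,218;225;300
EC 19,G,0.00,1,0.00,0.00,168
EC 20,H,0.00,1,0.00,0.00,181
EC 22,I,0.18,2,0.30,0.15,192;225
EC 23,J,0.22,2,0.34,0.18,224;240
EC 24,K,0.80,5,0.98,0.47,234;240;260;265;500;510
EC 27,L,0.75,3,1.08,0.58,287;295;340;345
EC 28,M,0.06,2,0.14,0.06,237;315
EC 31,N,0.96,4,0.98,0.49,160;164;200;210;250;280
EC 33,O,0.45,4,0.86,0.42,100;133;160;170
EC 34,P,0.82,4,1.01,0.51,150;170;191;240;250
EC 35,Q,0.06,2,0.13,0.05,200;350
EC 38,R,0.92,3,1.03,0.55,200;229;250
EC 39,S,0.00,2,0.62,0.33,155;275
EC 41,T,0.72,2,0.67,0.36,234;290
EC 47,U,0.69,3,0.84,0.43,200;220;245
EC 49,V,0.00,1,0.00,0.00,219;250
EC 50,W,0.00,1,0.00,0.00,223;250
EC 52,X,0.96,3,0.80,0.41,186;190;210
EC 54,Y,0.72,5,1.17,0.55,267;330;335;340;345
EC 55,Z,0.60,4,1.00,0.49,280;300;320;340
EC 56,AB,0.12,3,0.66,0.34,162;220
EC 57,AC,0.12,2,0.27,0.13,150;249
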