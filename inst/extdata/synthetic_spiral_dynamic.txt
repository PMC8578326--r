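502.16;493.82;0;484.129;30;1000;1
496.12;492.99;0;520.477;30;1008;1
490.02;494.85;0;527.417;30;1016;1
489.89;494.63;0;517.247;30;1024;1
493.67;497.72;0;537.923;30;1032;1
497.46;499.11;0;560.378;30;1040;1
507.92;497.27;0;264.579;30;1048;1
514.73;498.34;0;280.758;30;1056;1
521.59;498.49;0;272.720;30;1064;1
520.71;501.43;0;285.695;30;1072;1
513.85;505.42;0;282.815;30;1080;1
505.49;510.36;0;590.985;30;1088;1
492.51;516.55;0;608.638;30;1096;1
484.90;519.61;0;622.760;30;1104;1
477.12;519.65;0;626.079;30;1112;1
475.92;512.64;0;677.452;30;1120;1
477.25;501.18;0;669.295;30;1128;1
482.54;486.24;0;630.911;30;1136;1
490.94;474.03;0;683.930;30;1144;1
498.02;464.45;0;679.751;30;1152;1
508.60;460.64;0;691.442;30;1160;1
518.40;466.60;0;675.113;30;1168;1
526.03;482.29;0;687.534;30;1176;1
532.18;504.16;0;669.127;30;1184;1
533.12;524.00;0;730.307;30;1192;1
530.61;536.28;0;739.764;30;1200;1
518.77;546.21;0;722.267;30;1208;1
504.36;547.55;0;693.727;30;1216;1
480.72;536.73;0;701.021;30;1224;1
463.23;522.52;0;725.319;30;1232;1
450.80;501.30;0;696.353;30;1240;1
444.69;482.87;0;714.565;30;1248;1
450.58;466.04;0;685.402;30;1256;1
469.04;457.76;0;706.339;30;1264;1
496.22;450.81;0;696.270;30;1272;1
526.21;451.45;0;692.526;30;1280;1
550.48;462.27;0;726.266;30;1288;1
563.08;480.18;0;702.411;30;1296;1
567.21;499.80;0;679.946;30;1304;1
557.19;523.87;0;677.830;30;1312;1
533.93;546.69;0;683.604;30;1320;1
507.63;563.33;0;698.942;30;1328;1
474.91;570.43;0;673.465;30;1336;1
452.20;561.52;0;665.371;30;1344;1
434.81;541.53;0;359.264;30;1352;1
428.81;510.67;0;367.798;30;1360;1
434.71;474.72;0;364.750;30;1368;1
451.56;443.99;0;340.317;30;1376;1
476.10;418.43;0;365.951;30;1384;1
504.73;411.36;0;322.681;30;1392;1
532.95;420.81;0;322.577;30;1400;1
559.42;447.29;0;575.229;30;1408;1
576.92;485.00;0;561.739;30;1416;1
584.38;524.26;0;559.672;30;1424;1
574.06;561.21;0;550.411;30;1432;1
550.81;585.51;0;487.720;30;1440;1
513.77;593.41;0;532.042;30;1448;1
473.86;586.48;0;508.210;30;1456;1
435.99;564.99;0;475.320;30;1464;1
406.32;528.42;0;473.914;30;1472;1
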