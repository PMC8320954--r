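wavelength_nm,O2Hb,HHb
400,266.2,223.3
410,466.8,304.0
420,480.4,407.6
430,246.1,528.6
440,102.6,413.3
450,62.8,103.3
460,44.5,26.6
470,33.2,16.2
480,26.6,14.6
490,23.7,16.7
500,20.9,20.9
510,20.0,25.8
520,24.2,31.6
530,39.0,39.0
540,53.2,46.6
550,43.0,52.3
560,32.6,53.3
570,44.5,45.1
580,50.1,37.0
590,14.4,28.3
600,3.2,14.7
610,1.5,9.4
620,0.9,6.5
630,0.6,5.1
640,0.4,4.3
650,0.4,3.8
660,0.3,3.2
670,0.3,2.8
680,0.3,2.4
690,0.3,2.1
700,0.3,1.8
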