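##TITLE=CEF 10 ug/mL (synthetic band model)
##JCAMP-DX=4.24
##DATA TYPE=UV/VIS SPECTRUM
##XUNITS=NANOMETERS
##YUNITS=ABSORBANCE
##FIRSTX=210
##LASTX=300
##NPOINTS=91
##YFACTOR=1e-6
##XYDATA=(X++(Y..Y))
210 268680 299827 332620 366834 402194 438377 475018 511712
218 548019 583479 617615 649949 680010 707346 731540 752216
226 769052 781791 790245 794304 793936 789190 780195 767155
234 750341 730089 706784 680851 652746 622940 591910 560125
242 528034 496061 464592 433971 404495 376408 349902 325120
250 302152 281039 261783 244345 228654 214610 202094 190971
258 181096 172320 164493 157468 151106 145279 139868 134770
266 129893 125163 120517 115907 111297 106663 101993 97281
274 92531 87754 82965 78181 73425 68719 64086 59550
282 55132 50852 46728 42777 39010 35440 32072 28913
290 25965 23227 20697 18371 16243 14306 12551 10968
298 9548 8279 7151
##END=
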