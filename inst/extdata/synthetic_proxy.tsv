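time	value
5	-0.417367
10	-0.198133
15	-0.0305087
20	-0.0171182
25	-0.173154
30	-0.251828
35	-0.266176
40	-0.223513
45	-0.294783
50	-0.662774
55	-0.892885
60	-0.767391
65	-1.02785
70	-0.921834
75	-0.889984
80	-0.418249
85	-0.858188
90	-0.654078
95	-0.928051
100	-1.15441
105	-1.24725
110	-1.00658
115	-0.896613
120	-0.868111
125	-1.05248
130	-1.21102
135	-1.19057
140	-0.903768
145	-0.716657
150	-0.402539
155	-0.479963
160	-0.60711
165	-0.288436
170	0.00465705
175	-0.104372
180	-0.617488
185	-0.775208
190	-0.519278
195	-0.645748
200	-0.658283
205	-0.731026
210	-0.643313
215	-0.616959
220	-0.321606
225	-0.0892088
230	-0.394284
235	-0.674849
240	-0.605414
245	-0.587193
250	-0.152392
255	0.167158
260	-0.200932
265	-0.283177
270	-0.159933
275	0.283026
280	0.263487
285	0.72273
290	0.77785
295	0.552284
300	0.691297
305	0.674527
310	0.697585
315	0.697128
320	0.602074
325	0.583071
330	0.911554
335	0.803151
340	1.03275
345	0.793516
350	0.909522
355	0.598302
360	0.409312
365	0.607977
370	0.536559
375	0.729359
380	0.67127
385	0.53009
390	1.01502
395	0.808643
400	0.780118
405	0.627795
410	0.351913
415	0.371781
420	0.475065
425	0.226904
430	0.355345
435	0.0396382
440	-0.161783
445	-0.176106
450	-0.258433
455	-0.0993437
460	-0.331875
465	-0.24478
470	0.411799
475	0.36271
480	0.618853
485	0.266706
490	-0.0162254
495	0.00214852
500	-0.171587
505	0.15239
510	0.26288
515	0.6164
520	0.700503
525	0.454283
530	0.816189
535	0.781604
540	0.498974
545	0.319906
550	0.0136229
555	0.155429
560	0.0976997
565	0.0991024
570	0.0568121
575	0.295065
580	-0.210548
585	-0.105362
590	-0.0323121
595	0.145886
600	0.0164659
605	0.272323
610	0.0562515
615	0.0250621
620	-0.105378
625	0.0878387
630	0.422411
635	0.37615
640	0.537447
645	0.50961
650	0.752199
655	1.05591
660	1.05692
665	1.28237
670	1.16727
675	0.848435
680	0.760981
685	0.854073
690	1.08906
695	0.921527
700	0.780644
705	0.891887
710	0.508112
715	0.985912
720	0.881377
725	0.799875
730	0.903929
735	0.49783
740	0.407302
745	0.417368
750	0.108058
755	0.530325
760	0.0710623
765	-0.209392
770	-0.151866
775	-0.157149
780	-0.389125
785	-0.830713
790	-0.491255
795	-1.12127
800	-1.26785
805	-1.39239
810	-1.31791
815	-1.21511
820	-0.22399
825	0.419102
830	0.416485
835	0.155924
840	-0.0679663
845	0.40041
850	0.105414
855	0.462143
860	0.730521
865	0.388097
870	0.391619
875	0.398026
880	0.139325
885	0.286088
890	0.674933
895	1.06991
900	1.85196
905	1.65291
910	1.58733
915	1.57766
920	1.81002
925	1.82896
930	2.04272
935	1.8629
940	1.5414
945	1.25273
950	1.52689
955	1.76462
960	1.78692
965	1.98606
970	2.01858
975	1.93205
980	1.64125
985	1.80519
990	1.24825
995	1.22293
1000	1.59982
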