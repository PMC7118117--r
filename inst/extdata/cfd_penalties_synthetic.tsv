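position	spacer_base	offtarget_base	penalty
1	C	A	0.798
1	G	A	0.998
1	T	A	0.798
1	A	C	0.798
1	G	C	0.798
1	T	C	0.998
1	A	G	0.998
1	C	G	0.798
1	T	G	0.798
1	A	T	0.798
1	C	T	0.998
1	G	T	0.798
2	C	A	0.794
2	G	A	0.992
2	T	A	0.794
2	A	C	0.794
2	G	C	0.794
2	T	C	0.992
2	A	G	0.992
2	C	G	0.794
2	T	G	0.794
2	A	T	0.794
2	C	T	0.992
2	G	T	0.794
3	C	A	0.785
3	G	A	0.981
3	T	A	0.785
3	A	C	0.785
3	G	C	0.785
3	T	C	0.981
3	A	G	0.981
3	C	G	0.785
3	T	G	0.785
3	A	T	0.785
3	C	T	0.981
3	G	T	0.785
4	C	A	0.773
4	G	A	0.966
4	T	A	0.773
4	A	C	0.773
4	G	C	0.773
4	T	C	0.966
4	A	G	0.966
4	C	G	0.773
4	T	G	0.773
4	A	T	0.773
4	C	T	0.966
4	G	T	0.773
5	C	A	0.758
5	G	A	0.947
5	T	A	0.758
5	A	C	0.758
5	G	C	0.758
5	T	C	0.947
5	A	G	0.947
5	C	G	0.758
5	T	G	0.758
5	A	T	0.758
5	C	T	0.947
5	G	T	0.758
6	C	A	0.738
6	G	A	0.923
6	T	A	0.738
6	A	C	0.738
6	G	C	0.738
6	T	C	0.923
6	A	G	0.923
6	C	G	0.738
6	T	G	0.738
6	A	T	0.738
6	C	T	0.923
6	G	T	0.738
7	C	A	0.717
7	G	A	0.896
7	T	A	0.717
7	A	C	0.717
7	G	C	0.717
7	T	C	0.896
7	A	G	0.896
7	C	G	0.717
7	T	G	0.717
7	A	T	0.717
7	C	T	0.896
7	G	T	0.717
8	C	A	0.691
8	G	A	0.864
8	T	A	0.691
8	A	C	0.691
8	G	C	0.691
8	T	C	0.864
8	A	G	0.864
8	C	G	0.691
8	T	G	0.691
8	A	T	0.691
8	C	T	0.864
8	G	T	0.691
9	C	A	0.662
9	G	A	0.828
9	T	A	0.662
9	A	C	0.662
9	G	C	0.662
9	T	C	0.828
9	A	G	0.828
9	C	G	0.662
9	T	G	0.662
9	A	T	0.662
9	C	T	0.828
9	G	T	0.662
10	C	A	0.63
10	G	A	0.787
10	T	A	0.63
10	A	C	0.63
10	G	C	0.63
10	T	C	0.787
10	A	G	0.787
10	C	G	0.63
10	T	G	0.63
10	A	T	0.63
10	C	T	0.787
10	G	T	0.63
11	C	A	0.594
11	G	A	0.743
11	T	A	0.594
11	A	C	0.594
11	G	C	0.594
11	T	C	0.743
11	A	G	0.743
11	C	G	0.594
11	T	G	0.594
11	A	T	0.594
11	C	T	0.743
11	G	T	0.594
12	C	A	0.555
12	G	A	0.694
12	T	A	0.555
12	A	C	0.555
12	G	C	0.555
12	T	C	0.694
12	A	G	0.694
12	C	G	0.555
12	T	G	0.555
12	A	T	0.555
12	C	T	0.694
12	G	T	0.555
13	C	A	0.513
13	G	A	0.641
13	T	A	0.513
13	A	C	0.513
13	G	C	0.513
13	T	C	0.641
13	A	G	0.641
13	C	G	0.513
13	T	G	0.513
13	A	T	0.513
13	C	T	0.641
13	G	T	0.513
14	C	A	0.467
14	G	A	0.584
14	T	A	0.467
14	A	C	0.467
14	G	C	0.467
14	T	C	0.584
14	A	G	0.584
14	C	G	0.467
14	T	G	0.467
14	A	T	0.467
14	C	T	0.584
14	G	T	0.467
15	C	A	0.418
15	G	A	0.522
15	T	A	0.418
15	A	C	0.418
15	G	C	0.418
15	T	C	0.522
15	A	G	0.522
15	C	G	0.418
15	T	G	0.418
15	A	T	0.418
15	C	T	0.522
15	G	T	0.418
16	C	A	0.365
16	G	A	0.456
16	T	A	0.365
16	A	C	0.365
16	G	C	0.365
16	T	C	0.456
16	A	G	0.456
16	C	G	0.365
16	T	G	0.365
16	A	T	0.365
16	C	T	0.456
16	G	T	0.365
17	C	A	0.309
17	G	A	0.386
17	T	A	0.309
17	A	C	0.309
17	G	C	0.309
17	T	C	0.386
17	A	G	0.386
17	C	G	0.309
17	T	G	0.309
17	A	T	0.309
17	C	T	0.386
17	G	T	0.309
18	C	A	0.25
18	G	A	0.312
18	T	A	0.25
18	A	C	0.25
18	G	C	0.25
18	T	C	0.312
18	A	G	0.312
18	C	G	0.25
18	T	G	0.25
18	A	T	0.25
18	C	T	0.312
18	G	T	0.25
19	C	A	0.186
19	G	A	0.233
19	T	A	0.186
19	A	C	0.186
19	G	C	0.186
19	T	C	0.233
19	A	G	0.233
19	C	G	0.186
19	T	G	0.186
19	A	T	0.186
19	C	T	0.233
19	G	T	0.186
20	C	A	0.12
20	G	A	0.15
20	T	A	0.12
20	A	C	0.12
20	G	C	0.12
20	T	C	0.15
20	A	G	0.15
20	C	G	0.12
20	T	G	0.12
20	A	T	0.12
20	C	T	0.15
20	G	T	0.12
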