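Month,itch,scar
2004-01,82,38
2004-02,81,37
2004-03,84,40
2004-04,90,39
2004-05,87,41
2004-06,87,41
2004-07,95,43
2004-08,92,41
2004-09,86,39
2004-10,88,38
2004-11,84,39
2004-12,82,37
2005-01,85,37
2005-02,85,40
2005-03,91,40
2005-04,91,41
2005-05,92,44
2005-06,94,43
2005-07,99,43
2005-08,93,42
2005-09,91,41
2005-10,91,42
2005-11,90,40
2005-12,89,40
2006-01,89,40
2006-02,91,40
2006-03,93,42
2006-04,97,44
2006-05,97,43
2006-06,97,45
2006-07,100,45
2006-08,100,44
2006-09,98,44
2006-10,94,43
2006-11,96,42
2006-12,94,42
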