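year,concentration
1990.02,5.031
1990.11,6.158
1990.12,6.053
1990.32,5.073
1990.35,5.429
1990.5,6.095
1990.69,4.765
1991.23,5.247
1991.64,5.044
1992.8,5.536
1992.8,5.445
1993.08,6.068
1993.51,5.777
1993.71,4.91
1994.21,5.852
1994.62,5.059
1994.65,4.864
1995.05,6.073
1995.71,4.963
1995.89,5.891
1996.36,5.263
1996.83,6.67
1996.87,6.251
1997.14,5.615
1997.42,6.37
1998.21,6.241
1998.25,5.288
1998.52,5.899
1998.69,5.484
1998.8,6.326
1998.94,5.686
1999.32,5.98
1999.54,5.403
2000.9,5.731
2001.11,6.414
2001.13,5.736
2001.62,6.31
2001.72,6.507
2002.03,6.324
2003.84,6.486
2003.97,5.636
2004.62,6.591
2005.1,5.732
2006.97,7.728
2007.22,6.464
2007.5,7.189
2008.22,7.498
2008.57,7.232
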